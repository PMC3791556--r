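sample	status
S001	case
S002	case
S003	case
S004	case
S005	case
S006	case
S007	case
S008	case
S009	case
S010	case
S011	case
S012	case
S013	control
S014	control
S015	control
S016	control
S017	control
S018	control
S019	control
S020	control
S021	control
S022	control
S023	control
S024	control
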