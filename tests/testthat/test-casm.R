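make_tv <- function(ref, alt, cons) {
  data.frame(class = "aas", ref_aa = ref, alt_aa = alt,
             indel_kind = NA_character_, indel_length = NA_integer_,
             conservation = cons, stringsAsFactors = FALSE)
}

make_indel_tv <- function(kind, len) {
  data.frame(class = "indel", ref_aa = NA_character_,
             alt_aa = NA_character_, indel_kind = kind, indel_length = len,
             conservation = NA_real_, stringsAsFactors = FALSE)
}

test_that("endpoint likelihoods follow the conservation-mass definitions", {
  # two V>A variants with P = 1.0 and 0.5 in a disease set of C_D = 4
  disease <- rbind(make_tv("V", "A", 1.0), make_tv("V", "A", 0.5),
                   make_tv("L", "P", 0.8), make_tv("R", "*", 0.9))
  neutral <- rbind(make_tv("V", "A", 0.1), make_tv("S", "T", 0.2))
  cm <- train_casm(disease, neutral)
  i <- which(cm$aas$type == "V>A")
  expect_equal(cm$aas$a1[i], 0.375)   # (1.0 + 0.5) / 4
  expect_equal(cm$aas$a0[i], 0.125)   # (0.0 + 0.5) / 4
  # all variants of a type at P = 1: a1 = n_i / C_D, a0 = 0
  d2 <- rbind(make_tv("G", "R", 1), make_tv("G", "R", 1),
              make_tv("A", "T", 0.5))
  cm2 <- train_casm(d2, neutral)
  k <- which(cm2$aas$type == "G>R")
  expect_equal(cm2$aas$a1[k], 2 / 3)
  expect_equal(cm2$aas$a0[k], 0)
})

test_that("training matches a brute-force double-loop oracle exactly", {
  set.seed(101)
  types <- aas_types()
  rand_tv <- function(n) {
    idx <- sample.int(nrow(types), n, replace = TRUE)
    make_tv(types$ref_aa[idx], types$alt_aa[idx], round(runif(n), 3))
  }
  for (rep in 1:3) {
    disease <- rand_tv(40)
    neutral <- rand_tv(25)
    cm <- train_casm(disease, neutral)
    ora_d <- oracle_train_endpoints(disease)
    ora_n <- oracle_train_endpoints(neutral)
    for (key in names(ora_d)) {
      i <- which(cm$aas$type == key)
      expect_equal(cm$aas$a1[i], unname(ora_d[[key]]["e1"]))
      expect_equal(cm$aas$a0[i], unname(ora_d[[key]]["e0"]))
    }
    for (key in names(ora_n)) {
      i <- which(cm$aas$type == key)
      expect_equal(cm$aas$h1[i], unname(ora_n[[key]]["e1"]))
      expect_equal(cm$aas$h0[i], unname(ora_n[[key]]["e0"]))
    }
    # types absent from the training sets have zero raw endpoints
    absent <- setdiff(types$type, c(names(ora_d), names(ora_n)))
    rows <- match(absent, cm$aas$type)
    expect_true(all(cm$aas$a0[rows] == 0 & cm$aas$h1[rows] == 0))
  }
})

test_that("endpoint mass is normalized before pseudocounting", {
  set.seed(7)
  ts <- generate_training_sets(n_disease = 400, n_neutral = 300, seed = 7)
  cm <- train_casm(ts$disease, ts$neutral)
  # each AAS variant contributes P + (1 - P) = 1 mass in total
  expect_equal(sum(cm$aas$a0 + cm$aas$a1), 1)
  expect_equal(sum(cm$aas$h0 + cm$aas$h1), 1)
  expect_true(all(cm$aas$a0 >= 0 & cm$aas$a1 >= 0 &
                    cm$aas$h0 >= 0 & cm$aas$h1 >= 0))
  # indel proportions each sum to 1 as well
  expect_equal(sum(cm$indel$a), 1)
  expect_equal(sum(cm$indel$h), 1)
})

test_that("severity interpolation is linear with exact endpoints", {
  cm <- test_casm()
  r1 <- severity_ratio(cm, "L", "*", 1)
  r0 <- severity_ratio(cm, "L", "*", 0)
  i <- which(cm$aas$type == "L>*")
  expect_equal(r1, (cm$aas$a1[i] + cm$meta$eps_a) /
                 (cm$aas$h1[i] + cm$meta$eps_h))
  expect_equal(r0, (cm$aas$a0[i] + cm$meta$eps_a) /
                 (cm$aas$h0[i] + cm$meta$eps_h))
  # midpoint of endpoint ratios, and general linearity
  expect_equal(severity_ratio(cm, "L", "*", 0.5), (r1 + r0) / 2)
  for (x in c(0.1, 0.25, 0.7, 0.9)) {
    expect_equal(severity_ratio(cm, "L", "*", x), x * r1 + (1 - x) * r0)
  }
  # monotone increasing in x whenever r1 > r0
  expect_true(r1 > r0)
  xs <- seq(0, 1, 0.1)
  expect_true(all(diff(severity_ratio(cm, "L", "*", xs)) > 0))
  # out-of-range conservation is an error
  expect_error(severity_ratio(cm, "V", "A", 1.2), "\\[0, 1\\]")
  expect_error(severity_ratio(cm, "V", "A", -0.1), "\\[0, 1\\]")
  expect_error(severity_ratio(cm, "B", "A", 0.5), "unknown amino-acid")
})

test_that("types absent from one training set stay finite via pseudocounts", {
  disease <- rbind(make_tv("W", "C", 0.9), make_tv("W", "C", 0.7),
                   make_tv("A", "G", 0.2))
  neutral <- rbind(make_tv("A", "G", 0.3), make_tv("A", "G", 0.1))
  cm <- train_casm(disease, neutral)
  # W>C unseen in the neutral set: h endpoints are the raw zeros, the
  # ratio is (a + eps) / eps -- finite and positive
  i <- which(cm$aas$type == "W>C")
  expect_equal(cm$aas$h1[i], 0)
  s <- severity_ratio(cm, "W", "C", 0.8)
  expect_true(is.finite(s) && s > 0)
  # a type seen nowhere has severity (eps/eps interpolated)
  s0 <- severity_ratio(cm, "Y", "H", 0.5)
  expect_equal(s0, cm$meta$eps_a / cm$meta$eps_h)
})

test_that("discriminative training yields conservation-increasing severities", {
  # disease variants concentrated at high conservation, neutral at low:
  # enriched types must score higher at x = 1 than at x = 0
  ts <- generate_training_sets(n_disease = 3000, n_neutral = 3000,
                               seed = 99)
  cm <- train_casm(ts$disease, ts$neutral)
  aas_only <- ts$disease[ts$disease$class == "aas", ]
  counts <- table(paste0(aas_only$ref_aa, ">", aas_only$alt_aa))
  top <- names(sort(counts, decreasing = TRUE))[1:5]
  for (key in top) {
    i <- which(cm$aas$type == key)
    expect_gt(severity_ratio(cm, cm$aas$ref_aa[i], cm$aas$alt_aa[i], 1),
              severity_ratio(cm, cm$aas$ref_aa[i], cm$aas$alt_aa[i], 0))
  }
})

test_that("indel severity is the pseudocounted category-proportion ratio", {
  # build sets where one category has disease proportion 0.10 and neutral
  # proportion 0.02, with training sets large enough that eps is small
  n <- 5000
  disease <- rbind(
    make_indel_tv("deletion", rep(1, 0.10 * n)),          # frameshift len 1
    make_indel_tv("insertion", rep(3, 0.90 * n)))         # inframe len 3
  neutral <- rbind(
    make_indel_tv("deletion", rep(1, 0.02 * n)),
    make_indel_tv("insertion", rep(3, 0.98 * n)))
  cm <- train_casm(disease, neutral)
  s <- indel_severity(cm, "deletion", 1)
  eps_a <- cm$meta$eps_a_indel; eps_h <- cm$meta$eps_h_indel
  expect_equal(s, (0.10 + eps_a) / (0.02 + eps_h))
  expect_equal(s, 5, tolerance = 0.02)
  # category absent from both sets: severity 1 (eps/eps)
  expect_equal(indel_severity(cm, "insertion", 10),
               eps_a / eps_h)
  expect_equal(indel_severity(cm, "insertion", 10), 1, tolerance = 1e-12)
  # frameshift category with neutral proportion 0: finite via eps floor
  disease2 <- make_indel_tv("deletion", rep(2, 50))
  neutral2 <- make_indel_tv("deletion", rep(3, 50))
  cm2 <- train_casm(rbind(disease2, make_tv("V", "A", 0.5)),
                    rbind(neutral2, make_tv("V", "A", 0.5)))
  s2 <- indel_severity(cm2, "deletion", 2)
  expect_true(is.finite(s2) && s2 > 1)
  # unknown category errors
  expect_error(indel_severity(cm, "inversion", 2), "kind")
})

test_that("severity matrices round-trip losslessly through TSV", {
  cm <- test_casm()
  path <- tempfile(fileext = ".tsv")
  save_casm(cm, path)
  cm2 <- load_casm(path)
  expect_equal(cm2$aas$a0, cm$aas$a0)
  expect_equal(cm2$aas$a1, cm$aas$a1)
  expect_equal(cm2$aas$h0, cm$aas$h0)
  expect_equal(cm2$aas$h1, cm$aas$h1)
  expect_equal(cm2$indel$a, cm$indel$a)
  expect_equal(cm2$indel$h, cm$indel$h)
  expect_equal(cm2$meta$eps_a, cm$meta$eps_a)
  # identical severities before and after the round trip
  set.seed(3)
  types <- aas_types()[sample.int(420, 25), ]
  x <- runif(25)
  expect_equal(severity_ratio(cm2, types$ref_aa, types$alt_aa, x),
               severity_ratio(cm, types$ref_aa, types$alt_aa, x))
  expect_equal(indel_severity(cm2, "deletion", 1:12),
               indel_severity(cm, "deletion", 1:12))
  # a file with a missing column is a parse error naming the column
  tab <- readLines(path)
  hdr_i <- grep("^class\t", tab)
  body <- strsplit(tab[hdr_i:length(tab)], "\t")
  broken <- vapply(body, function(f) paste(f[-4], collapse = "\t"), "")
  writeLines(c(tab[seq_len(hdr_i - 1)], broken), path)
  expect_error(load_casm(path), "alt_aa")
})

test_that("empty training sets and unknown symbols are rejected", {
  ok <- make_tv("V", "A", 0.5)
  expect_error(train_casm(ok[0, ], ok), "non-empty")
  expect_error(train_casm(ok, ok[0, ]), "non-empty")
  expect_error(train_casm(make_tv("Z", "A", 0.5), ok), "Z")
  expect_error(train_casm(make_tv("V", "A", 1.5), ok), "\\[0, 1\\]")
})
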