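# A small deterministic cohort exercising every cascade branch, plus a
# classifier trained on well-separated synthetic copy-number profiles.
make_cascade_fixture <- function() {
  train <- simulate_cohort(n = 80, seed = 31, n_genes = 60)
  model <- ec_classifier(train$cn, train$clinical$cn_cluster == 4,
                         train$genes)
  mk_variants <- function(ids, n_snv, ca_frac, cg_frac) {
    do.call(rbind, lapply(seq_along(ids), function(i) {
      n <- n_snv[i]
      n_ca <- round(ca_frac[i] * n)
      n_cg <- round(cg_frac[i] * n)
      ref <- rep("C", n)
      alt <- c(rep("A", n_ca), rep("G", n_cg), rep("T", n - n_ca - n_cg))
      data.frame(sample = ids[i], chromosome = "1", position = seq_len(n),
                 ref = ref, alt = alt, stringsAsFactors = FALSE)
    }))
  }
  list(model = model, train = train, mk_variants = mk_variants)
}

as_variants <- function(df) {
  df$variant_class <- variant_class(df$ref, df$alt)
  structure(df, class = c("somatic_variants", "data.frame"))
}

quiet_cn <- function(ids, ploidy = 2) {
  seg <- do.call(rbind, lapply(ids, function(id)
    seg_row(id, "1", 1, 1e6, ploidy)))
  make_cn(seg)
}

clin_row <- function(ids, msi) {
  data.frame(sample = ids, msi_status = msi, msi_score = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("the cascade applies strict precedence POLE > MSI > CN-high > CN-low", {
  fx <- make_cascade_fixture()
  ids <- c("P1", "M1", "L1")
  v <- as_variants(fx$mk_variants(ids, c(600, 100, 100),
                                  c(0.25, 0.05, 0.05), c(0.01, 0.02, 0.02)))
  # P1 is POLE-positive AND MSI-high: POLE wins by precedence
  cl <- clin_row(ids, c("MSI-high", "MSI-high", "MSS"))
  calls <- predict(fx$model, v, cl, quiet_cn(ids))
  got <- stats::setNames(as.character(calls$subtype), calls$sample)
  expect_equal(got[["P1"]], "POLE")
  expect_equal(got[["M1"]], "MSI")
  expect_equal(got[["L1"]], "CN-low")  # quiet profile, MSS
  # evidence trail: POLE/MSI rows leave the posterior unset by default
  expect_true(is.na(calls$cn_high_posterior[calls$sample == "P1"]))
  expect_false(is.na(calls$cn_high_posterior[calls$sample == "L1"]))
  expect_equal(calls$snv_count[calls$sample == "P1"], 600L)
})

test_that("a CN-high profile is called CN-high only after POLE and MSI pass", {
  fx <- make_cascade_fixture()
  # pick the training CN-high samples' profiles as test input
  hi <- fx$train$labels$sample[fx$train$labels$subtype == "CN-high"][1:3]
  cn <- subset_cn <- fx$train$cn
  cn$segments <- cn$segments[cn$segments$sample %in% hi, ]
  cn$ploidy <- cn$ploidy[hi]
  v <- as_variants(fx$mk_variants(hi, rep(100, 3), rep(0.05, 3),
                                  rep(0.02, 3)))
  cl <- clin_row(hi, "MSS")
  calls <- predict(fx$model, v, cl, cn)
  expect_true(all(calls$subtype == "CN-high"))
  expect_true(all(calls$cn_high_posterior >= 0.5))
  # the same profiles under an MSI-high flag become MSI
  cl2 <- clin_row(hi, "MSI-high")
  calls2 <- predict(fx$model, v, cl2, cn)
  expect_true(all(calls2$subtype == "MSI"))
})

test_that("every sample gets exactly one of the four labels", {
  co <- simulate_cohort(n = 60, seed = 17, n_genes = 60)
  fx_model <- ec_classifier(co$cn, co$clinical$cn_cluster == 4, co$genes)
  calls <- predict(fx_model, co$variants, co$clinical, co$cn)
  expect_equal(nrow(calls), 60)
  expect_false(anyNA(calls$subtype))
  expect_true(all(calls$subtype %in% c("POLE", "MSI", "CN-low", "CN-high")))
})

test_that("classification is insensitive to input row order", {
  fx <- make_cascade_fixture()
  ids <- c("A1", "B1", "C1")
  v <- as_variants(fx$mk_variants(ids, c(700, 50, 50),
                                  c(0.3, 0.05, 0.05), c(0.01, 0.02, 0.02)))
  cl <- clin_row(ids, c("MSS", "MSI-high", "MSS"))
  cn <- quiet_cn(ids)
  c1 <- predict(fx$model, v, cl, cn)
  c2 <- predict(fx$model, v[rev(seq_len(nrow(v))), ], cl[c(3, 1, 2), ], cn)
  expect_equal(c1, c2)
})

test_that("duplicating samples under new ids reproduces each label", {
  fx <- make_cascade_fixture()
  ids <- c("A1", "B1")
  v <- fx$mk_variants(ids, c(700, 80), c(0.3, 0.05), c(0.01, 0.02))
  v2 <- v; v2$sample <- paste0(v2$sample, "dup")
  vv <- as_variants(rbind(v, v2))
  cl <- clin_row(c(ids, paste0(ids, "dup")),
                 rep(c("MSS", "MSI-high"), 2))
  cn <- quiet_cn(c(ids, paste0(ids, "dup")))
  calls <- predict(fx$model, vv, cl, cn)
  lab <- stats::setNames(as.character(calls$subtype), calls$sample)
  expect_equal(unname(lab[c("A1", "B1")]),
               unname(lab[c("A1dup", "B1dup")]))
})

test_that("mismatched sample universes raise an error naming the ids", {
  fx <- make_cascade_fixture()
  ids <- c("A1", "B1")
  v <- as_variants(fx$mk_variants(ids, c(100, 100), c(.05, .05), c(.02, .02)))
  cl <- clin_row("A1", "MSS")  # B1 missing from clinical
  expect_error(predict(fx$model, v, cl, quiet_cn(ids)), "B1")
})

test_that("missing MSI status errors only for samples that reach the gate", {
  fx <- make_cascade_fixture()
  ids <- c("P1", "U1")
  v <- as_variants(fx$mk_variants(ids, c(700, 100), c(0.3, 0.05),
                                  c(0.01, 0.02)))
  cl <- clin_row(ids, c("unknown", "unknown"))
  # U1 is non-POLE and lacks MSI status -> error names it
  expect_error(predict(fx$model, v, cl, quiet_cn(ids)), "U1")
  # a POLE sample with unknown MSI is fine: resolved before the gate
  cl2 <- clin_row(ids, c("unknown", "MSS"))
  calls <- predict(fx$model, v, cl2, quiet_cn(ids))
  expect_equal(as.character(calls$subtype[calls$sample == "P1"]), "POLE")
})

test_that("the posterior threshold separates CN-high from CN-low only", {
  fx <- make_cascade_fixture()
  ids <- "X1"
  v <- as_variants(fx$mk_variants(ids, 100, 0.05, 0.02))
  cl <- clin_row(ids, "MSS")
  lo <- predict(fx$model, v, cl, quiet_cn(ids))
  expect_equal(as.character(lo$subtype), "CN-low")
  # same sample, high-alteration profile -> flips to CN-high, never to
  # POLE or MSI (counterfactual monotonicity)
  hi_id <- fx$train$labels$sample[fx$train$labels$subtype == "CN-high"][1]
  seg <- fx$train$cn$segments
  seg <- seg[seg$sample == hi_id, ]
  seg$sample <- "X1"
  cn_hi <- make_cn(seg, ploidy = c(X1 = unname(fx$train$cn$ploidy[hi_id])))
  hi <- predict(fx$model, v, cl, cn_hi)
  expect_equal(as.character(hi$subtype), "CN-high")
})

test_that("full_evidence computes the posterior for short-circuited samples", {
  fx <- make_cascade_fixture()
  ids <- c("P1", "M1")
  v <- as_variants(fx$mk_variants(ids, c(700, 100), c(0.3, 0.05),
                                  c(0.01, 0.02)))
  cl <- clin_row(ids, c("MSS", "MSI-high"))
  cn <- quiet_cn(ids)
  a <- predict(fx$model, v, cl, cn)
  b <- predict(fx$model, v, cl, cn, full_evidence = TRUE)
  expect_true(all(is.na(a$cn_high_posterior)))
  expect_false(anyNA(b$cn_high_posterior))
  expect_equal(a$subtype, b$subtype)
})

test_that("a fitted model round-trips through its JSON file", {
  fx <- make_cascade_fixture()
  p <- tempfile(fileext = ".json")
  write_ec_model(fx$model, p)
  back <- read_ec_model(p)
  expect_equal(back$nb$mean, fx$model$nb$mean, tolerance = 1e-12)
  expect_equal(back$nb$var, fx$model$nb$var, tolerance = 1e-12)
  expect_equal(back$selected_genes, fx$model$selected_genes)
  expect_equal(back$pole$snv_min, fx$model$pole$snv_min)
  # identical predictions from the restored model
  co <- simulate_cohort(n = 20, seed = 4, n_genes = 60,
                        genes = fx$train$genes)
  c1 <- predict(fx$model, co$variants, co$clinical, co$cn)
  c2 <- predict(back, co$variants, co$clinical, co$cn)
  expect_equal(c1$subtype, c2$subtype)
  expect_equal(c1$cn_high_posterior, c2$cn_high_posterior, tolerance = 1e-10)
  expect_error(read_ec_model(write_tsv(data.frame(a = 1))), "model file")
})
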