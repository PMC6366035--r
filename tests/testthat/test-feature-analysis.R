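test_that("sequence composition features are computed on the right spans", {
  ft <- compute_mirna_features(c(m1 = "GGCC"), seed_span = c(1, 4))
  expect_equal(ft$gc_mature, 100)
  # seed GC of mature miR-21 over positions 2-8 (AGCUUAU): 2 of 7
  ft21 <- compute_mirna_features(c(mir21 = MIR21_MATURE))
  expect_equal(ft21$gc_seed, 100 * 2 / 7, tolerance = 1e-12)
  expect_identical(ft21$mature_length, nchar(MIR21_MATURE))
  expect_true(all(ft21$gc_mature >= 0 & ft21$gc_mature <= 100))
})

test_that("dot-bracket features follow the declared structural conventions", {
  pre <- "GCGCAAAAGCGC"
  st  <- "((((....))))"
  ft <- compute_mirna_features(c(x = pre), premirnas = c(x = pre),
                               structures = c(x = st))
  expect_identical(ft$n_complementary_fragments, 1L)
  expect_equal(ft$mean_complementary_fragment_length, 4)
  expect_identical(ft$n_unpaired_fragments, 1L)  # the loop, mature = full
  expect_identical(ft$hairpin_length, 4L)        # 5' arm paired span
  expect_identical(ft$n_gc_pairs, 4L)
  expect_error(compute_mirna_features(c(x = pre), premirnas = c(x = pre),
                                      structures = c(x = "(((...)))")),
               "length differ")
  expect_error(mirimpact:::parse_dot_bracket("(()"), "unbalanced")
  expect_error(mirimpact:::parse_dot_bracket("())"), "unbalanced")
})

test_that("targeted-transcript counts and expression join the feature table", {
  Cp <- matrix(c(0, 1.2, 0.4, 0, 0, 0), 3, 2,
               dimnames = list(paste0("t", 1:3), c("m1", "m2")))
  ft <- compute_mirna_features(c(m1 = "ACGUACGUACGU", m2 = "UGCAUGCAUGCA"),
                               targets = Cp, expr = c(m1 = 5.5, m2 = 9))
  expect_equal(ft$n_targeted_transcripts, c(2, 0))
  expect_equal(ft$expression, c(5.5, 9))
})

test_that("dk-sign split matches an elementwise sign oracle", {
  dk <- c(a = 0.01, b = -0.02, c = 0, d = 0.003)
  gr <- split_by_dk_sign(dk)
  expect_identical(gr$positive, names(dk)[dk > 0])
  expect_identical(gr$negative, names(dk)[dk < 0])
  expect_identical(gr$zero, "c")
  set.seed(4)
  r <- setNames(rnorm(50), paste0("m", 1:50))
  gr2 <- split_by_dk_sign(r)
  expect_setequal(c(gr2$positive, gr2$negative, gr2$zero), names(r))
})

test_that("Mann-Whitney U equals exhaustive enumeration for small groups", {
  set.seed(77)
  for (rep in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    a <- sample(0:6, n1, replace = TRUE)  # integer samples: ties guaranteed
    b <- sample(0:6, n2, replace = TRUE)
    got <- mann_whitney_u(a, b)
    # oracle U: direct pairwise comparison count
    u_oracle <- 0
    for (x in a) for (y in b) u_oracle <- u_oracle + (x > y) + 0.5 * (x == y)
    expect_equal(got$U, u_oracle)
    # oracle p: enumerate all group assignments from scratch
    pooled <- c(a, b)
    combs <- combn(n1 + n2, n1)
    us <- apply(combs, 2, function(ix) {
      aa <- pooled[ix]; bb <- pooled[-ix]
      sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
    })
    mu <- n1 * n2 / 2
    p_oracle <- mean(abs(us - mu) >= abs(u_oracle - mu) - 1e-12)
    expect_equal(got$p_value, p_oracle)
    expect_identical(got$method, "exact enumeration")
  }
})

test_that("Mann-Whitney agrees with wilcox.test on tie-free data", {
  set.seed(15)
  for (rep in 1:10) {
    a <- rnorm(6); b <- rnorm(7, 0.5)
    got <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
  # identical groups: U at its null mean, p = 1
  same <- c(1, 3, 5, 7)
  got <- mann_whitney_u(same, same)
  expect_equal(got$U, length(same)^2 / 2)
  expect_equal(got$p_value, 1)
})

test_that("large-sample Mann-Whitney approximation detects a 2-sigma shift", {
  set.seed(33)
  a <- rnorm(50); b <- rnorm(50, 2)
  got <- mann_whitney_u(a, b)
  expect_identical(got$method, "normal approximation")
  expect_lt(got$p_value, 0.05)
  # and the t-test route through compare_groups flags it too
  feats <- data.frame(id = paste0("m", 1:100), v = c(a, b))
  cmp_t <- compare_groups(feats, paste0("m", 1:50), paste0("m", 51:100),
                          test = "two_sample_t")
  expect_lt(cmp_t$p_value[cmp_t$feature == "v"], 0.05)
  cmp_u <- compare_groups(feats, paste0("m", 1:50), paste0("m", 51:100),
                          test = "mann_whitney_u")
  expect_true(cmp_u$significant[cmp_u$feature == "v"])
  expect_error(compare_groups(feats, character(0), "m1"), "non-empty")
})

test_that("fit classification respects the boundary rule and is nested", {
  obs <- c(t1 = 1.0, t2 = 1.0, t3 = 0)
  pred <- c(t1 = 0.51, t2 = 0.49, t3 = 0)
  cl <- classify_mrna_fit(obs, pred, cutoff = 0.5)
  expect_identical(cl$good_ids, c("t1", "t3"))  # error 0.49 is good
  expect_identical(cl$poor_ids, "t2")           # error 0.51 is poor
  # boundary exactly at the cutoff counts as good
  expect_true("t1" %in% classify_mrna_fit(obs, c(t1 = 0.5, t2 = 0, t3 = 0),
                                          0.5)$good_ids)
  expect_error(classify_mrna_fit(obs, pred[1:2]), "equal length")
  expect_error(classify_mrna_fit(obs, pred, cutoff = 0), "positive")
  # elementwise oracle and nesting across an increasing grid
  set.seed(20)
  o <- rnorm(100); p <- o + rnorm(100, 0, 0.5)
  names(o) <- names(p) <- paste0("g", 1:100)
  prev <- character(0)
  for (ct in c(0.2, 0.5, 0.8)) {
    cli <- classify_mrna_fit(o, p, ct)
    expect_setequal(cli$good_ids, names(o)[abs(o - p) <= ct])
    expect_true(all(prev %in% cli$good_ids))
    prev <- cli$good_ids
  }
})

test_that("cutoff sweep tracks group sizes and planted covariates", {
  set.seed(25)
  n <- 300
  obs <- rnorm(n); names(obs) <- paste0("g", 1:n)
  pred <- obs + rnorm(n, 0, 0.4)
  err <- abs(obs - pred)
  ann <- data.frame(transcript_id = names(obs),
                    utr_len = 1500 - 400 * err + rnorm(n, 0, 50),
                    unrelated = rnorm(n))
  sw <- sweep_fit_cutoff(obs, pred, ann, cutoffs = seq(0.2, 1, by = 0.2))
  # single-point grid reduces to classify + compare
  one <- sweep_fit_cutoff(obs, pred, ann, cutoffs = 0.5)
  cl <- classify_mrna_fit(obs, pred, 0.5)
  expect_identical(unique(one$n_good), length(cl$good_ids))
  # good-fit group grows with the cutoff
  sizes <- unique(sw[, c("cutoff", "n_good")])
  expect_true(all(diff(sizes$n_good) >= 0))
  # the planted covariate separates the groups; the unrelated one does not
  p_utr <- sw$p_value[sw$feature == "utr_len"]
  p_unrel <- sw$p_value[sw$feature == "unrelated"]
  expect_lt(min(p_utr), 0.05)
  expect_gt(min(p_unrel), min(p_utr))
  expect_error(sweep_fit_cutoff(obs, pred, ann, cutoffs = c(0.5, 0.2)),
               "increasing")
  expect_error(sweep_fit_cutoff(obs, pred, ann, cutoffs = c(-1, 0.5)),
               "positive")
})
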