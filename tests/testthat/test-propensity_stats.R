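test_that("composition counts by hand, including degenerate strata", {
  tb <- composition(c(1, 1, 0, 0), "mdab")
  df <- tb$table
  expect_equal(df$freq_interface[df$symbol == "m"], 0.5)
  expect_equal(df$freq_interface[df$symbol == "d"], 0.5)
  expect_equal(df$freq_outside[df$symbol == "a"], 0.5)
  expect_equal(df$freq_outside[df$symbol == "b"], 0.5)
  expect_equal(df$freq_interface[df$symbol %in% c("a", "b")], c(0, 0))
  # all-binding: outside column zero-flagged
  expect_warning(tb2 <- composition(c(1, 1, 1, 1), "mmdd"), "all-zero")
  expect_equal(tb2$table$freq_interface[tb2$table$symbol == "m"], 0.5)
  expect_true(all(tb2$table$freq_outside == 0))
})

test_that("composition columns are normalised on random fixtures", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    enc <- sample(letters[1:12], n, replace = TRUE)
    lab <- runif(n) < 0.5
    if (!any(lab) || all(lab)) next
    tb <- composition(lab, enc, alphabet = letters[1:12])
    expect_equal(sum(tb$table$freq_interface), 1, tolerance = 1e-9)
    expect_equal(sum(tb$table$freq_outside), 1, tolerance = 1e-9)
    expect_true(all(tb$table$freq_interface >= 0))
  }
})

test_that("log-odds preference: identity, hand arithmetic, pseudocount finiteness", {
  # identical interface and outside counts -> 0 everywhere
  enc <- c(rep("m", 10), rep("d", 20), rep("m", 10), rep("d", 20))
  lab <- rep(c(TRUE, FALSE), c(30, 30))
  lo <- log_odds_preference(composition(lab, enc), pseudocount = 0)
  expect_equal(unname(lo$values), c(0, 0), tolerance = 1e-12)
  # 20/100 vs 10/100 at alpha = 0 -> ln 2
  enc <- c(rep("m", 20), rep("x", 80), rep("m", 10), rep("x", 90))
  lab <- rep(c(TRUE, FALSE), c(100, 100))
  lo <- log_odds_preference(composition(lab, enc), pseudocount = 0)
  expect_equal(unname(lo$values["m"]), log(2), tolerance = 1e-12)
  # zero interface count stays finite (and negative) with a pseudocount
  enc <- c(rep("d", 50), rep("m", 5), rep("d", 45))
  lab <- rep(c(TRUE, FALSE), c(50, 50))
  lo <- log_odds_preference(composition(lab, enc, alphabet = c("d", "m")),
                            pseudocount = 1)
  expect_true(is.finite(lo$values[["m"]]))
  expect_lt(lo$values[["m"]], 0)
})

test_that("MIP: independence zeros, hand cell, brute-force oracle, permutation", {
  # exact product table -> all zeros at alpha = 0
  counts <- rbind(c(12, 8), c(18, 12))
  dimnames(counts) <- list(c("m", "d"), c("a", "b"))
  m0 <- mip_from_counts(counts, pseudocount = 0)
  expect_equal(max(abs(m0$propensity)), 0, tolerance = 1e-12)
  # hand arithmetic on a 2x2
  counts <- rbind(c(30, 10), c(10, 50))
  dimnames(counts) <- list(c("m", "d"), c("a", "b"))
  m1 <- mip_from_counts(counts, pseudocount = 0)
  expect_equal(m1$propensity["m", "a"], log(30 * 100 / (40 * 40)),
               tolerance = 1e-12)
  # brute-force oracle on random tables, both pseudocounts
  set.seed(5)
  for (rep in 1:20) {
    R <- sample(2:6, 1); C <- sample(2:5, 1)
    cnt <- matrix(rpois(R * C, 20), R, C,
                  dimnames = list(letters[1:R], LETTERS[1:C]))
    for (a in c(0, 1)) {
      got <- mip_from_counts(cnt, a)$propensity
      for (i in 1:R) for (j in 1:C) {
        want <- log((cnt[i, j] + a) * (sum(cnt) + a * R * C) /
                      ((sum(cnt[i, ]) + a * C) * (sum(cnt[, j]) + a * R)))
        expect_equal(got[i, j], want, tolerance = 1e-12)
      }
    }
  }
  # count semantics: order of the contact list is irrelevant
  pairs <- cbind(sample(c("m", "d"), 200, TRUE), sample(c("a", "b"), 200, TRUE))
  m2 <- mip(pairs, c("m", "d"), c("a", "b"))
  m3 <- mip(pairs[sample(200), ], c("m", "d"), c("a", "b"))
  expect_identical(m2$counts, m3$counts)
  expect_equal(m2$propensity, m3$propensity)
  expect_error(mip(matrix(character(0), ncol = 2), "m", "a"), "empty")
})

test_that("planted enrichment factors are recovered as ln(r) at large n", {
  # noise-free planted draws; interface frequency of the boosted letter is
  # exactly r x background, so the log-odds estimate converges to ln(r)
  for (r in c(2, 4)) {
    spec <- planted_spec(n_complexes = 63, protein_length = 160,
                         plc_enrich = c(m = r), rlc_enrich = c(b = 1),
                         seq_enrich = c(R = 1), noise = 0,
                         protein_interface_frac = 0.48, seed = 400 + r)
    bs <- generate_bundles(spec)
    enc <- unlist(lapply(bs, function(b) strsplit(b$protein$plc, "")[[1]]))
    lab <- unlist(lapply(bs, function(b) b$protein$labels))
    expect_gte(length(lab), 10000)
    lo <- log_odds_preference(
      composition(lab, enc, alphabet = c(letters[1:16], "Z")), pseudocount = 1)
    expect_equal(unname(lo$values["m"]), log(r), tolerance = 0.1)
  }
})

test_that("stratify: per-class tables, additivity, planted stratum signal", {
  spec_e <- strong_planted_spec(21, n_complexes = 6, class_tag = "enzymes")
  spec_r <- planted_spec(plc_enrich = c(m = 1), rlc_enrich = c(b = 1),
                         seq_enrich = c(R = 1), n_complexes = 12,
                         class_tag = "regulatory", seed = 22)
  bs <- c(generate_bundles(spec_e), generate_bundles(spec_r))
  # distinct ids across strata for grouping semantics
  for (k in 7:18) bs[[k]]$id <- paste0(bs[[k]]$id, "r")
  st <- stratify(bs)
  expect_setequal(names(st), c("enzymes", "regulatory", "pooled"))
  # pooled counts are the elementwise sum of the strata counts
  for (al in c("aa", "plc", "rlc", "nt")) {
    expect_equal(st$pooled$composition[[al]]$table$count_interface,
                 st$enzymes$composition[[al]]$table$count_interface +
                   st$regulatory$composition[[al]]$table$count_interface)
  }
  # the planted helix-block enrichment shows only in the enzymes stratum
  expect_gt(st$enzymes$log_odds$plc$values[["m"]], 0.5)
  expect_lt(abs(st$regulatory$log_odds$plc$values[["m"]]), 0.35)
  # single stratum equals pooled
  st1 <- stratify(generate_bundles(spec_e))
  expect_equal(st1$enzymes$composition$plc$table,
               st1$pooled$composition$plc$table)
  # unknown tags rejected
  bad <- generate_bundles(spec_e, 2)
  bad[[1]]$class_tag <- "mystery"
  expect_error(stratify(bad), "unknown class tag")
})

test_that("propensity tables export as tidy TSV", {
  st <- stratify(generate_bundles(planted_spec(n_complexes = 3, seed = 8)))
  tf <- tempfile(fileext = ".tsv")
  write_propensities(st, tf)
  out <- read.delim(tf)
  expect_true(all(c("alphabet", "stratum", "symbol", "freq_interface",
                    "log_odds") %in% names(out)))
  expect_true(all(is.finite(out$log_odds)))
})
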