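# shared fixture: a small bundle set and fitted tables
local_bundles <- function(seed = 77, n = 6) {
  generate_bundles(strong_planted_spec(seed, n_complexes = n,
                                       protein_length = 30, rna_length = 20))
}

test_that("one sample per position, constant vector length, stable re-encoding", {
  bs <- local_bundles()
  for (w in c(3, 5, 7, 9)) {
    cfg <- rpi_feature_config(window = w)
    tb <- fit_feature_tables(bs, cfg)
    ps <- encode_protein_windows(bs[[1]], cfg, tb)
    rs <- encode_rna_windows(bs[[1]], cfg, tb)
    expect_identical(nrow(ps$features), 30L)
    expect_identical(nrow(rs$features), 20L)
    expect_true(all(!is.na(ps$features)))
    # slices partition the vector
    expect_identical(sort(unname(unlist(ps$groups))),
                     seq_len(ncol(ps$features)))
    expect_identical(sort(unname(unlist(rs$groups))),
                     seq_len(ncol(rs$features)))
    # bit-identical on re-encoding
    ps2 <- encode_protein_windows(bs[[1]], cfg, tb)
    expect_identical(ps$features, ps2$features)
  }
  expect_error(rpi_feature_config(window = 4), "window")
})

test_that("window composition features count k-mers by hand", {
  bs <- local_bundles()
  cfg <- rpi_feature_config()
  tb <- fit_feature_tables(bs, cfg)
  b <- bs[[1]]
  b$rna$seq <- paste0("AAACG", strrep("U", 15))
  rs <- encode_rna_windows(b, cfg, tb)
  f3 <- rs$features[3, ]  # window = positions 1..5 = "AAACG"
  expect_equal(unname(f3[c("mono:A", "mono:C", "mono:G", "mono:U")]),
               c(0.6, 0.2, 0.2, 0))
  expect_equal(unname(f3["di:AA"]), 0.5)  # AA,AA,AC,CG
  expect_equal(unname(f3["tri:AAA"]), 1 / 3)
  b$rna$seq <- strrep("A", 20)
  rs <- encode_rna_windows(b, cfg, tb)
  expect_equal(unname(rs$features[10, "di:AA"]), 1)
  expect_equal(sum(rs$features[10, rs$groups$di]), 1)
  # mono/di/tri blocks each sum to 1 in every window
  rs <- encode_rna_windows(bs[[2]], cfg, tb)
  for (g in c("mono", "di", "tri"))
    expect_equal(unname(rowSums(rs$features[, rs$groups[[g]]])),
                 rep(1, 20), tolerance = 1e-12)
})

test_that("terminal windows use neutral padding", {
  bs <- local_bundles()
  cfg <- rpi_feature_config()
  tb <- fit_feature_tables(bs, cfg)
  ps <- encode_protein_windows(bs[[1]], cfg, tb)
  # the two pad positions of residue 1 carry the chain mean of each scalar
  kd <- ps$features[, ps$groups$physchem]
  chain_mean <- mean(kd[, "physchem:kd_w0"])
  expect_equal(unname(ps$features[1, "physchem:kd_w-2"]), chain_mean)
  expect_equal(unname(ps$features[1, "physchem:kd_w-1"]), chain_mean)
  expect_equal(unname(ps$features[2, "physchem:kd_w-2"]), chain_mean)
})

test_that("toggling a family removes exactly its slice and nothing else", {
  bs <- local_bundles()
  cfg_all <- rpi_feature_config()
  tb <- fit_feature_tables(bs, cfg_all)
  full <- encode_protein_windows(bs[[1]], cfg_all, tb)
  cfg_off <- rpi_feature_config(with_structure = FALSE)
  bare <- encode_protein_windows(bs[[1]], cfg_off, tb)
  expect_identical(ncol(bare$features),
                   ncol(full$features) - length(full$groups$plc_triplet))
  keep <- setdiff(seq_len(ncol(full$features)), full$groups$plc_triplet)
  expect_identical(bare$features, full$features[, keep])
  expect_false("plc_triplet" %in% names(bare$groups))
})

test_that("triplet log-odds: symmetry zero, planted ratio, unseen triplets", {
  # equally frequent in both classes -> 0
  tab <- fit_triplet_log_odds(list("mmmm", "mmmm"), list(c(F, T, T, F),
                                                         c(F, F, F, T)),
                              alphabet = letters[1:16], pseudocount = 1e-9)
  expect_equal(unname(tab$values["mmm"]), 0, tolerance = 1e-6)
  # a triplet planted 4x more often at binding centres recovers ~ln(4)
  set.seed(19)
  n_chain <- 2000
  draw <- function(p_mmm) ifelse(runif(n_chain) < p_mmm, "mmm", "ddd")
  strings <- c(draw(0.4), draw(0.1))
  labs <- c(rep(list(c(FALSE, TRUE, FALSE)), n_chain),
            rep(list(c(FALSE, FALSE, FALSE)), n_chain))
  tab <- fit_triplet_log_odds(as.list(strings), labs,
                              alphabet = letters[1:16], pseudocount = 1)
  expect_equal(unname(tab$values["mmm"]), log(4), tolerance = 0.15)
  # unseen triplet: finite pseudocount-only value; foreign symbols: 0
  expect_true(is.finite(triplet_value(tab, "aaa")))
  expect_identical(triplet_value(tab, "a?a"), 0)
  expect_error(fit_triplet_log_odds(list(), list(), letters[1:12]),
               "empty training set")
})

test_that("pair encoding concatenates protein-then-RNA with contact labels", {
  bs <- local_bundles()
  cfg <- rpi_feature_config()
  tb <- fit_feature_tables(bs, cfg)
  b <- bs[[1]]
  ps <- encode_protein_windows(b, cfg, tb)
  rs <- encode_rna_windows(b, cfg, tb)
  ct <- b$contacts$contacts
  pairs <- rbind(c(ct$residue[1], ct$nucleotide[1]),
                 c(which(!b$protein$labels)[1], which(!b$rna$labels)[1]))
  pr <- encode_pair(ps, rs, pairs, b$contacts)
  expect_identical(ncol(pr$features), ncol(ps$features) + ncol(rs$features))
  expect_identical(pr$labels, c(TRUE, FALSE))
  expect_identical(pr$side, "pair")
  # protein slice comes first and matches the member rows
  expect_equal(unname(pr$features[1, seq_len(ncol(ps$features))]),
               unname(ps$features[pairs[1, 1], ]))
  expect_equal(unname(pr$features[2, -seq_len(ncol(ps$features))]),
               unname(rs$features[pairs[2, 2], ]))
  # swapping one member of a non-contact pair changes only that side's slice
  pr2 <- encode_pair(ps, rs, rbind(pairs[2, ], c(pairs[2, 1], pairs[2, 2])),
                     b$contacts)
  alt <- which(!b$rna$labels)[2]
  pr3 <- encode_pair(ps, rs, rbind(pairs[2, ], c(pairs[2, 1], alt)),
                     b$contacts)
  pslice <- seq_len(ncol(ps$features))
  expect_identical(pr3$features[2, pslice], pr2$features[2, pslice])
})

test_that("mismatched sample sets are rejected when combined", {
  bs <- local_bundles()
  tb <- fit_feature_tables(bs, rpi_feature_config())
  a <- encode_protein_windows(bs[[1]], rpi_feature_config(), tb)
  b <- encode_protein_windows(bs[[2]], rpi_feature_config(window = 7), tb)
  expect_error(bind_samples(list(a, b)), "layout")
})
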