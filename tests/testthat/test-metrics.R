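test_that("model accuracy matches a hand formula on a printed 4x4 pair", {
  A <- matrix(c(1, .2, .3, .4,
                .2, 1, .5, .6,
                .3, .5, 1, .7,
                .4, .6, .7, 1), 4, byrow = TRUE)
  B <- matrix(c(1, .1, .4, .3,
                .1, 1, .6, .4,
                .4, .6, 1, .9,
                .3, .4, .9, 1), 4, byrow = TRUE)
  acc <- model_accuracy(A, B)
  a <- c(.2, .3, .5, .4, .6, .7)       # upper triangle, column-major
  b <- c(.1, .4, .6, .3, .4, .9)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(acc$r, r_hand, tolerance = 1e-12)
  expect_equal(acc$mse, mean((a - b)^2), tolerance = 1e-12)
  expect_equal(acc$n_pairs, 6)

  expect_equal(model_accuracy(A, A)$r, 1)
  expect_equal(model_accuracy(A, A)$mse, 0)
  # sign-flipped (zero-mean) triangle anti-correlates perfectly
  a0 <- A; a0[upper.tri(a0)] <- a0[upper.tri(a0)] - mean(a0[upper.tri(a0)])
  a0[lower.tri(a0)] <- t(a0)[lower.tri(a0)]
  neg <- a0; neg[upper.tri(neg)] <- -neg[upper.tri(neg)]
  neg[lower.tri(neg)] <- t(neg)[lower.tri(neg)]
  expect_equal(model_accuracy(a0, neg)$r, -1)
  expect_warning(model_accuracy(diag(4), diag(4)), "constant")
})

test_that("z-abnormality matches entrywise brute force and its identities", {
  set.seed(2)
  healthy <- lapply(1:4, function(i) toy_fc(3, seed = i))
  mu <- Reduce(`+`, healthy) / 4
  z0 <- z_abnormality(mu, healthy)
  expect_equal(max(abs(z0), na.rm = TRUE), 0, tolerance = 1e-12)

  sd_ <- sqrt(Reduce(`+`, lapply(healthy, function(h) (h - mu)^2)) / 3)
  subj <- mu + sd_
  z1 <- z_abnormality(subj, healthy)
  off <- !diag(3)
  expect_equal(unclass(z1)[off], rep(1, 6), tolerance = 1e-12)

  patient <- toy_fc(3, seed = 99)
  z <- z_abnormality(patient, healthy)
  for (i in 1:3) for (j in 1:3) {
    vals <- vapply(healthy, function(h) h[i, j], numeric(1))
    if (stats::sd(vals) == 0) {
      expect_true(is.na(z[i, j]))
    } else {
      expect_equal(z[i, j], (patient[i, j] - mean(vals)) / stats::sd(vals),
                   tolerance = 1e-12)
    }
  }
  expect_error(z_abnormality(patient, healthy[1:2]), "at least 3")
})

test_that("intra-hemispheric DAN-DMN FC averages the right pairs", {
  parc <- make_parcellation(8, 2)        # 2 DAN + 2 DMN per hemisphere
  fc <- matrix(0.3, 8, 8); diag(fc) <- 1
  expect_equal(intra_dan_dmn_fc(fc, parc), 0.3)
  # enumeration oracle on a toy matrix
  fc2 <- toy_fc(8, seed = 5)
  vals <- c()
  for (i in which(parc$network == "DAN")) {
    for (j in which(parc$network == "DMN")) {
      if (parc$hemisphere[i] == parc$hemisphere[j]) vals <- c(vals, fc2[i, j])
    }
  }
  expect_equal(intra_dan_dmn_fc(fc2, parc), mean(vals), tolerance = 1e-12)
  # no same-hemisphere DAN-DMN pair: DAN only on the left, DMN only on the right
  bad <- parcellation(
    region_id = c("L1", "L2", "R1", "R2"),
    hemisphere = c("left", "left", "right", "right"),
    network = c("DAN", "DAN", "DMN", "DMN")
  )
  expect_error(intra_dan_dmn_fc(fc2[1:4, 1:4], bad), "no same-hemisphere")
})

test_that("homotopic FC averages within network then across networks", {
  parc <- make_parcellation(8, 2)
  fc <- matrix(0.1, 8, 8); diag(fc) <- 1
  hp <- homotopic_pairs(parc)
  fc[cbind(hp$i, hp$j)] <- fc[cbind(hp$j, hp$i)] <- 0.8
  expect_equal(inter_homotopic_fc(fc, parc), 0.8)
  # per-network means 0.6 and 0.2 average to 0.4
  fc2 <- matrix(0, 8, 8); diag(fc2) <- 1
  for (k in seq_len(nrow(hp))) {
    v <- if (hp$network[k] == "DAN") 0.6 else 0.2
    fc2[hp$i[k], hp$j[k]] <- fc2[hp$j[k], hp$i[k]] <- v
  }
  expect_equal(inter_homotopic_fc(fc2, parc), 0.4)
  # flat mean differs when networks have unequal pair counts
  parc3 <- make_parcellation(12, 3)
  fc3 <- toy_fc(12, seed = 2)
  hp3 <- homotopic_pairs(parc3)
  expect_equal(inter_homotopic_fc(fc3, parc3, per_network = FALSE),
               mean(fc3[cbind(hp3$i, hp3$j)]), tolerance = 1e-12)
  nopairs <- parcellation(c("L1", "R1"), c("left", "right"), c("DAN", "DMN"))
  expect_error(inter_homotopic_fc(diag(2), nopairs), "no homotopic pairs")
})

test_that("fixed-partition Newman modularity matches brute force and igraph", {
  # two 3-cliques, no between edges, matching partition: Q = 0.5
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  parc <- parcellation(
    region_id = paste0("r", 1:6),
    hemisphere = "left",
    network = rep(c("DAN", "DMN"), each = 3)
  )
  expect_equal(fc_modularity(A, parc), 0.5, tolerance = 1e-12)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  expect_equal(fc_modularity(A, parc),
               igraph::modularity(g, rep(1:2, each = 3)), tolerance = 1e-12)
  # single-module partition: Q = 0
  parc1 <- parcellation(paste0("r", 1:6), "left", "DAN")
  expect_equal(fc_modularity(A, parc1), 0, tolerance = 1e-12)
  # true modular partition beats a random one on a seeded modular graph
  co <- small_cohorts()
  fc <- empirical_fc(co$healthy_runs)
  q_true <- fc_modularity(fc, co$parcellation)
  set.seed(4)
  parc_rand <- co$parcellation
  parc_rand$network <- sample(parc_rand$network)
  expect_gt(q_true, fc_modularity(fc, parc_rand))
  # weighted cross-check against igraph on a thresholded FC graph
  Athr <- unclass(fc); Athr[Athr < 0] <- 0; diag(Athr) <- 0
  gw <- igraph::graph_from_adjacency_matrix(Athr, mode = "undirected",
                                            weighted = TRUE)
  memb <- as.integer(factor(co$parcellation$network))
  expect_equal(fc_modularity(fc, co$parcellation),
               igraph::modularity(gw, memb, weights = igraph::E(gw)$weight),
               tolerance = 1e-10)
  expect_error(fc_modularity(matrix(-1, 3, 3) + diag(3) * 0, parc1[1:3, ]),
               "empty graph")
})

test_that("global efficiency hits its exact graph oracles", {
  complete <- matrix(1, 5, 5); diag(complete) <- 0
  expect_equal(global_efficiency(complete, binarize = FALSE), 1)
  empty <- matrix(0, 5, 5)
  expect_equal(global_efficiency(empty, binarize = FALSE), 0)
  # 3-node path: distances (1,1,2) -> E = (1 + 1 + 1/2) * 2 / 6 = 5/6
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_efficiency(path3, binarize = FALSE), 5 / 6)
  expect_error(global_efficiency(matrix(0, 1, 1)), "at least 2")
  # monotone non-decreasing under edge addition
  set.seed(6)
  A <- matrix(0, 12, 12)
  pairs <- which(upper.tri(A))
  e_prev <- 0
  for (k in sample(pairs, 25)) {
    A[k] <- 1
    B <- A + t(A) > 0
    e_now <- global_efficiency(B * 1, binarize = FALSE)
    expect_gte(e_now, e_prev - 1e-12)
    e_prev <- e_now
  }
})

test_that("FC entropy is normalized and matches a hand-computed histogram", {
  one_bin <- matrix(0.5, 6, 6); diag(one_bin) <- 1
  expect_equal(fc_entropy(one_bin, m_bins = 10), 0)
  # exactly uniform counts across 5 bins -> H = 1
  v <- c(0.1, 0.3, 0.5, 0.7, 0.9, 0.11, 0.31, 0.51, 0.71, 0.91)
  M <- diag(5); M[upper.tri(M)] <- v; M[lower.tri(M)] <- t(M)[lower.tri(M)]
  expect_equal(fc_entropy(M, m_bins = 5), 1)
  # 10 listed |FC| values, m = 4: direct histogram + formula oracle
  vals <- c(0.05, 0.12, 0.18, 0.25, 0.33, 0.42, 0.55, 0.61, 0.72, 0.95)
  counts <- c(sum(vals < 0.25), sum(vals >= 0.25 & vals < 0.5),
              sum(vals >= 0.5 & vals < 0.75), sum(vals >= 0.75))
  p <- counts / sum(counts)
  h_hand <- -sum(p[p > 0] * log(p[p > 0])) / log(4)
  M2 <- diag(5); M2[upper.tri(M2)] <- vals; M2[lower.tri(M2)] <- t(M2)[lower.tri(M2)]
  expect_equal(fc_entropy(M2, m_bins = 4), h_hand, tolerance = 1e-12)
  # sign-invariant: uses |FC|
  expect_equal(fc_entropy(-M2, m_bins = 4), fc_entropy(M2, m_bins = 4))
  expect_true(fc_entropy(toy_fc(10, 3), 50) >= 0 &&
                fc_entropy(toy_fc(10, 3), 50) <= 1)
  expect_error(fc_entropy(M2, m_bins = 1), "m_bins")
})

test_that("average degree counts binarized edges per node", {
  complete <- matrix(1, 6, 6); diag(complete) <- 0
  expect_equal(average_degree(complete, binarize = FALSE), 5)
  expect_equal(average_degree(matrix(0, 6, 6), binarize = FALSE), 0)
  # seeded graph vs enumeration through the same threshold
  fc <- toy_fc(10, seed = 7)
  B <- binarize_fc(fc, 0.25)
  expect_equal(average_degree(fc, 0.25), mean(rowSums(B)))
  expect_equal(sum(B != t(B)), 0)
  # proportional mode keeps the requested edge count
  Bp <- binarize_fc(fc, 0.1, method = "proportional")
  expect_equal(sum(Bp) / 2, round(0.1 * choose(10, 2)))
})

test_that("signature abnormality scores reduce to masked means of z", {
  parc <- make_parcellation(8, 2)
  z0 <- matrix(0, 8, 8)
  s <- signature_abnormality(z0, parc)
  expect_equal(unlist(s), c(homotopic_z = 0, dan_dmn_z = 0))
  z2 <- matrix(2, 8, 8)
  s2 <- signature_abnormality(z2, parc)
  expect_equal(unlist(s2), c(homotopic_z = 2, dan_dmn_z = 2))
  zr <- toy_fc(8, seed = 9)
  s3 <- signature_abnormality(zr, parc)
  expect_equal(s3$homotopic_z, inter_homotopic_fc(zr, parc))
  expect_equal(s3$dan_dmn_z, intra_dan_dmn_fc(zr, parc))
})

test_that("fc_metric_record assembles one row of all per-subject metrics", {
  co <- small_cohorts()
  fc <- empirical_fc(co$healthy_runs[1])
  rec <- fc_metric_record(fc, co$parcellation, "H01")
  expect_equal(nrow(rec), 1)
  expect_true(rec$fc_entropy >= 0 && rec$fc_entropy <= 1)
  expect_true(rec$global_efficiency >= 0 && rec$global_efficiency <= 1)
  expect_equal(rec$intra_dan_dmn_fc, intra_dan_dmn_fc(fc, co$parcellation))
})
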