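test_that("make_parcellation builds balanced mirrored hemispheres", {
  p <- make_parcellation(8, 2)
  expect_equal(sum(p$hemisphere == "left"), 4)
  expect_equal(sum(p$hemisphere == "right"), 4)
  expect_equal(nrow(homotopic_pairs(p)), 4)
  # L3's partner is R3 and vice versa
  expect_equal(p$homotopic_partner[p$region_id == "L003"], "R003")
  expect_equal(p$homotopic_partner[p$region_id == "R003"], "L003")
  # networks mirrored across hemispheres
  expect_equal(p$network[p$hemisphere == "left"],
               p$network[p$hemisphere == "right"])
  expect_error(make_parcellation(8, 5), "may not exceed")
  expect_error(make_parcellation(9, 2), "even")
})

test_that("synthetic structural connectome satisfies its contract", {
  cfg <- synthetic_study_config(seed = 1)
  parc <- make_parcellation(40, 4)
  sc <- make_structural_connectome(parc, cfg)
  W <- unclass(sc)
  expect_equal(max(W), 0.2)
  expect_equal(W, t(W))
  expect_equal(diag(W), rep(0, 40), ignore_attr = TRUE)
  expect_true(all(W >= 0))
  # connected as a graph
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  expect_equal(igraph::components(g)$no, 1)
  # within-network coupling stronger than between (seed-1 values pinned)
  same <- outer(parc$network, parc$network, `==`)
  ut <- upper.tri(W)
  expect_equal(mean(W[same & ut]), 0.0749, tolerance = 1e-2)
  expect_equal(mean(W[!same & ut]), 0.0054, tolerance = 1e-1)
  expect_gt(mean(W[same & ut]), mean(W[!same & ut]))
  # homotopic pairs carry the strongest weights on average
  hp <- homotopic_pairs(parc)
  expect_gt(mean(W[cbind(hp$i, hp$j)]), mean(W[same & ut]))
})

test_that("ground-truth GEC perturbation preserves sparsity and adds asymmetry", {
  parc <- make_parcellation(20, 4)
  cfg <- synthetic_study_config(n_regions = 20, seed = 4)
  sc <- make_structural_connectome(parc, cfg)
  expect_equal(make_ground_truth_gec(sc, sd = 0, seed = 1)[, ],
               unclass(sc)[, ], ignore_attr = TRUE)
  g1 <- make_ground_truth_gec(sc, sd = 0.4, seed = 1)
  expect_identical(unclass(g1) > 0, unclass(sc) > 0)
  expect_gt(asymmetry_index(g1), 0)
})

test_that("synthetic lesions follow the core/spillover spared semantics", {
  parc <- make_parcellation(40, 4)
  cfg <- synthetic_study_config(seed = 6)
  sc <- make_structural_connectome(parc, cfg)
  m <- make_lesion(parc, cfg, seed = 21, structural = sc)
  core <- attr(m, "core")
  S <- unclass(m)
  expect_equal(S, t(S))
  expect_equal(diag(S), rep(1, 40), ignore_attr = TRUE)
  expect_true(all(S >= 0 & S <= 1))
  # core stays within one hemisphere, contiguous in index
  expect_true(all(diff(sort(core)) == 1))
  hemis <- unique(parc$hemisphere[core])
  expect_length(hemis, 1)
  # fully severed pairs have both endpoints in the core (enumerate)
  sev <- which(S == 0 & upper.tri(S), arr.ind = TRUE)
  expect_true(all(sev[, 1] %in% core & sev[, 2] %in% core))
  # untouched pairs (both outside core) are fully spared
  outside <- setdiff(seq_len(40), core)
  expect_true(all(S[outside, outside] == 1))
  # spillover only where streamlines exist
  one_end <- outer(seq_len(40) %in% core, seq_len(40) %in% core, xor)
  partial <- S < 1 & S > 0
  expect_true(all(unclass(sc)[partial & one_end] > 0))
})

test_that("degenerate lesions: empty core spares everything, full core severs everything", {
  parc <- make_parcellation(10, 2)
  cfg <- synthetic_study_config(n_regions = 10, n_networks = 2, seed = 1)
  n <- 10
  # empty core: spared must be identically 1 (build directly)
  m0 <- sdc_mask(matrix(1, n, n), parc)
  expect_equal(total_disconnection(m0), 0)
  # total lesion: all off-diagonal severed
  S <- matrix(0, n, n); diag(S) <- 1
  m1 <- sdc_mask(S, parc)
  expect_equal(total_disconnection(m1), n)
})

test_that("cohorts are deterministic and healthy subjects invariant to n_patients", {
  cfg <- synthetic_study_config(n_regions = 12, n_networks = 2, n_healthy = 3,
                                n_patients = 2, run_length_timepoints = 120,
                                seed = 9)
  c1 <- make_cohorts(cfg)
  c2 <- make_cohorts(cfg)
  expect_identical(unclass(c1$healthy_runs[[2]])[, ],
                   unclass(c2$healthy_runs[[2]])[, ])
  expect_identical(unclass(c1$masks[[1]])[, ], unclass(c2$masks[[1]])[, ])
  expect_identical(c1$behaviour, c2$behaviour)

  cfg4 <- synthetic_study_config(n_regions = 12, n_networks = 2, n_healthy = 3,
                                 n_patients = 4, run_length_timepoints = 120,
                                 seed = 9)
  c3 <- make_cohorts(cfg4)
  expect_identical(unclass(c1$healthy_runs[[3]])[, ],
                   unclass(c3$healthy_runs[[3]])[, ])
})

test_that("behaviour couples negatively to total disconnection at zero noise", {
  cfg <- synthetic_study_config(n_regions = 16, n_networks = 2, n_healthy = 1,
                                n_patients = 8, run_length_timepoints = 60,
                                behaviour_noise_sd = 0, seed = 13)
  co <- make_cohorts(cfg)
  b <- co$behaviour[co$behaviour$domain == "domain_a", ]
  tds <- co$total_disconnection[b$patient_id]
  expect_true(stats::sd(tds) > 0)
  expect_lt(stats::cor(b$score, tds), 0)
})

test_that("synthetic healthy FC shows the homotopic inter-hemispheric signature", {
  co <- small_cohorts()
  fc <- empirical_fc(co$healthy_runs)
  parc <- co$parcellation
  hp <- homotopic_pairs(parc)
  homot <- mean(fc[cbind(hp$i, hp$j)])
  inter <- outer(parc$hemisphere, parc$hemisphere, `!=`)
  hmask <- matrix(FALSE, nrow(parc), nrow(parc))
  hmask[cbind(hp$i, hp$j)] <- hmask[cbind(hp$j, hp$i)] <- TRUE
  non_homot <- mean(fc[inter & !hmask & upper.tri(fc)])
  expect_gt(homot, non_homot)
})

test_that("a synthetic study serializes to a directory with a manifest", {
  dir <- withr::local_tempdir()
  co <- make_cohorts(synthetic_study_config(
    n_regions = 8, n_networks = 2, n_healthy = 2, n_patients = 2,
    run_length_timepoints = 60, seed = 3))
  write_synthetic_study(co, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 3)
  expect_true(all(file.exists(file.path(dir, unlist(man$files)))))
  sc_back <- read_matrix_tsv(file.path(dir, "structural.tsv"))
  expect_equal(sc_back[, ], unclass(co$structural)[, ], tolerance = 1e-12)
})
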