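test_that("aggregation follows the stated averaging conventions", {
  tt <- tiny_tables()
  f <- aggregate_features(tt$spines, tt$segments)
  r1 <- f[f$case_id == 1]
  # density: per-segment densities (2/20, 2/25 spines) averaged
  expect_equal(r1$mean_density, mean(c(10 * 2 / 20, 10 * 2 / 25)))
  # morphology: pooled over the case's spines
  expect_equal(r1$mean_head_diameter, mean(c(0.25, 0.50, 0.22, 0.45)))
  expect_equal(r1$mean_volume, mean(c(0.02, 0.10, 0.03, 0.08)))
  expect_equal(r1$n_spines, 4L)
  expect_equal(r1$n_neurons, 2L)
  expect_equal(r1$total_dendrite_um, 45)
  # per-class cells restrict to the class; empty cells are missing
  expect_equal(r1$thin_head_diameter, mean(c(0.25, 0.22)))
  expect_true(is.na(r1$filopodia_head_diameter))
  expect_equal(f[f$case_id == 2]$mean_head_diameter, 0.55)

  const <- data.table::copy(tt$spines)
  const[, "head_diameter_um" := 0.4]
  fc <- aggregate_features(const, tt$segments)
  expect_equal(fc$mean_head_diameter, c(0.4, 0.4))
})

test_that("class spine counts and densities decompose the totals", {
  co <- small_ba37_cohort()
  f <- aggregate_features(co$spines, co$segments)
  cls_dens <- as.matrix(f[, paste0(spine_classes(), "_density"),
                          with = FALSE])
  expect_equal(rowSums(cls_dens), f$mean_density, tolerance = 1e-12)
  cnt <- co$spines[, list(n = .N), by = "case_id"]
  m <- merge(cnt, f, by = "case_id")
  expect_equal(m$n, m$n_spines)
})

test_that("pooled aggregation equals a brute-force flat recomputation", {
  co <- small_ba37_cohort()
  f <- aggregate_features(co$spines, co$segments)
  sp <- as.data.frame(co$spines)
  sg <- as.data.frame(co$segments)
  for (cid in c(3, 57, 101)) {
    s <- sp[sp$case_id == cid, ]
    g <- sg[sg$case_id == cid, ]
    counts <- sapply(seq_len(nrow(g)), function(i)
      sum(s$neuron_id == g$neuron_id[i] & s$segment_id == g$segment_id[i]))
    expect_equal(f[f$case_id == cid]$mean_density,
                 mean(10 * counts / g$length_um))
    expect_equal(f[f$case_id == cid]$mean_length, mean(s$length_um))
    expect_equal(f[f$case_id == cid]$mushroom_volume,
                 mean(s$volume_um3[s$spine_class == "mushroom"]))
  }
})

test_that("aggregation is invariant to input row order", {
  tt <- tiny_tables()
  f1 <- aggregate_features(tt$spines, tt$segments)
  set.seed(1)
  f2 <- aggregate_features(tt$spines[sample(nrow(tt$spines))],
                           tt$segments[sample(nrow(tt$segments))])
  expect_equal(as.data.frame(f1), as.data.frame(f2))
})

test_that("per-neuron aggregation averages neuron means", {
  tt <- tiny_tables()
  f <- aggregate_features(tt$spines, tt$segments,
                          aggregation = "per_neuron")
  expect_equal(f[f$case_id == 1]$mean_head_diameter,
               mean(c(mean(c(0.25, 0.50)), mean(c(0.22, 0.45)))))
})

test_that("analysis table selects exactly one region from multi-region features", {
  tt <- tiny_tables()
  sp2 <- data.table::copy(tt$spines)[, "region" := "BA6"]
  sg2 <- data.table::copy(tt$segments)[, "region" := "BA6"]
  f <- aggregate_features(rbind(tt$spines, sp2), rbind(tt$segments, sg2))
  expect_equal(nrow(f), 4)  # 2 cases x 2 regions
  cases <- data.table::data.table(case_id = 1:2, episodic_memory = c(0, 1))
  at <- analysis_table(f, cases, "BA37")
  expect_equal(nrow(at), 2)
  expect_true(all(at$region == "BA37"))
  expect_error(analysis_table(f, cases, "BA46"), "no feature rows")
})

test_that("complete-case filtering removes exactly the missing cases", {
  cases <- data.table::data.table(
    case_id = 1:6, np_score = c(1, NA, 2, 3, 1, 2),
    nft_burden = c(1, 1, NA, 2, 2, 1),
    episodic_memory = c(0.1, 0.2, 0.3, NA, 0.5, 0.6))
  suppressMessages(out <- filter_complete_cases(cases))
  expect_equal(out$case_id, c(1L, 5L, 6L))
  expect_equal(attr(out, "removed_cases"), c(2L, 3L, 4L))

  full <- cases[c(1, 5, 6)]
  suppressMessages(expect_equal(filter_complete_cases(full)$case_id,
                                full$case_id))
  allna <- data.table::copy(cases)[, "np_score" := NA_real_]
  suppressMessages(expect_warning(out0 <- filter_complete_cases(allna),
                                  "all cases removed"))
  expect_equal(nrow(out0), 0)
  expect_error(filter_complete_cases(cases, required = "braak"),
               "absent")
})

test_that("discovery/validation split is a seeded partition", {
  cases <- data.table::data.table(case_id = 1:125, x = rnorm(125))
  sp <- split_discovery_validation(cases, seed = 111)
  expect_equal(nrow(sp$discovery), 63)
  expect_equal(nrow(sp$validation), 62)
  expect_length(intersect(sp$discovery$case_id, sp$validation$case_id), 0)
  expect_setequal(c(sp$discovery$case_id, sp$validation$case_id), 1:125)

  sp2 <- split_discovery_validation(cases, seed = 111)
  expect_identical(sp$discovery$case_id, sp2$discovery$case_id)
  sp3 <- split_discovery_validation(cases, seed = 7)
  expect_false(identical(sp$discovery$case_id, sp3$discovery$case_id))

  four <- data.table::data.table(case_id = 1:4)
  s4 <- split_discovery_validation(four, seed = 1)
  expect_equal(c(nrow(s4$discovery), nrow(s4$validation)), c(2L, 2L))
  expect_error(split_discovery_validation(four[1], seed = 1), "at least 2")
})
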