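# Preprocessing, batch adjustment, screening, BH, shadow-feature selection
# and the synthetic cohort generator.

test_that("preprocess filters on the 10-missing rule and imputes medians", {
  n_samp <- 93
  mk_species <- function(name, n_missing) {
    area <- stats::runif(n_samp, 50, 150)
    area[seq_len(n_missing)] <- NA
    tibble::tibble(
      sample = sprintf("S%02d", 1:n_samp), species = name,
      lipid_class = "PC", area = area
    )
  }
  set.seed(3)
  dat <- dplyr::bind_rows(
    mk_species("drop-me", 10), # missing in 10 samples: filtered out
    mk_species("keep-me", 9), # missing in 9: retained and imputed
    mk_species("full", 0)
  )
  out <- preprocess(dat)
  expect_false("drop-me" %in% out$species)
  expect_true("keep-me" %in% out$species)
  expect_false(anyNA(out$area))
  imputed <- out$area[out$species == "keep-me"][1:9]
  med <- stats::median(dat$area[dat$species == "keep-me"], na.rm = TRUE)
  expect_equal(imputed, rep(med, 9))
  # class columns sum to one per sample after normalization
  sums <- out |>
    dplyr::group_by(sample, lipid_class) |>
    dplyr::summarise(s = sum(norm_area), .groups = "drop")
  expect_equal(sums$s, rep(1, nrow(sums)))
  all_na <- tibble::tibble(
    sample = c("a", "b"), species = "x", lipid_class = "PC", area = NA_real_
  )
  expect_error(preprocess(all_na), "all values missing")
})

test_that("a toy imputation example works by hand", {
  dat <- tibble::tibble(
    sample = rep(c("s1", "s2", "s3"), each = 2),
    species = rep(c("a", "b"), 3),
    lipid_class = "PC",
    area = c(10, 30, NA, 50, 30, 70)
  )
  out <- preprocess(dat, missing_sample_cutoff = 2)
  # species a median across samples = median(10, 30) = 20
  expect_equal(out$area[out$species == "a" & out$sample == "s2"], 20)
  expect_equal(
    out$norm_area[out$sample == "s2"],
    c(20 / 70, 50 / 70)
  )
})

test_that("batch location shifts are removed in the large-n regime", {
  set.seed(5)
  G <- 40
  n <- 400
  batch <- factor(rep(c("A", "B"), each = n / 2))
  delta <- stats::rnorm(G, 0, 1)
  x <- matrix(stats::rnorm(G * n, 10, 1), G, n)
  x[, batch == "B"] <- x[, batch == "B"] + delta
  adj <- combat_adjust(x, batch)
  batch_gap <- rowMeans(adj[, batch == "B"]) - rowMeans(adj[, batch == "A"])
  expect_lt(max(abs(batch_gap)), 0.05)
  # output preserves dimensions
  expect_equal(dim(adj), dim(x))
})

test_that("identical batches are left essentially unchanged", {
  set.seed(6)
  x0 <- matrix(stats::rnorm(30 * 20, 5, 1), 30, 20)
  x <- cbind(x0, x0)
  batch <- factor(rep(c("A", "B"), each = 20))
  adj <- combat_adjust(x, batch)
  expect_equal(adj, x, tolerance = 0.02)
})

test_that("the EB adjustment matches the reference ComBat implementation", {
  skip_if_not_installed("sva")
  set.seed(42)
  G <- 50
  n <- 24
  batch <- factor(rep(c("A", "B", "C"), each = 8))
  group <- factor(rep(rep(c("g1", "g2"), each = 4), 3))
  x <- matrix(stats::rnorm(G * n, 8, 1), G, n)
  x <- x + outer(stats::rnorm(G, 0, 0.2), as.numeric(batch == "B") * 0.8)
  mine <- combat_adjust(x, batch, stats::model.matrix(~group)[, -1, drop = FALSE])
  theirs <- suppressMessages(
    sva::ComBat(x, batch = batch, mod = stats::model.matrix(~group))
  )
  expect_equal(mine, theirs, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("simulated batch effects are reduced below 1% explained variance", {
  set.seed(7)
  G <- 60
  n <- 90
  batch <- factor(rep(c("A", "B", "C"), each = n / 3))
  delta <- outer(rep(1, G), c(0, 1.2, -0.8)) + matrix(stats::rnorm(G * 3, 0, 0.1), G, 3)
  phi <- c(1, 1.6, 0.7)
  x <- matrix(0, G, n)
  for (b in 1:3) {
    idx <- which(as.integer(batch) == b)
    x[, idx] <- 8 + delta[, b] + phi[b] * matrix(stats::rnorm(G * length(idx)), G)
  }
  frac_batch_var <- function(m) {
    mean(apply(m, 1, function(y) summary(stats::lm(y ~ batch))$r.squared))
  }
  expect_gt(frac_batch_var(x), 0.05)
  expect_lt(frac_batch_var(combat_adjust(x, batch)), 0.01)
})

test_that("confounded batch and group designs are rejected", {
  x <- matrix(stats::rnorm(40), 4, 10)
  batch <- factor(rep(c("A", "B"), each = 5))
  group <- stats::model.matrix(~ factor(rep(c("g1", "g2"), each = 5)))[, -1, drop = FALSE]
  expect_error(combat_adjust(x, batch, group), "confounded")
  expect_error(combat_adjust(x, factor(rep("A", 10))), ">= 2 batches")
})

test_that("the Wilcoxon screen applies exact p-values and the FC gate", {
  meta <- tibble::tibble(
    sample = sprintf("s%d", 1:6),
    group = factor(rep(c("deficient", "normal"), each = 3), c("deficient", "normal"))
  )
  # fully separated 3 vs 3: exact two-sided p = 2 / choose(6, 3) = 0.10
  sep <- tibble::tibble(
    sample = meta$sample, species = "x", lipid_class = "PC",
    adj_area = c(10, 11, 12, 1, 2, 3)
  )
  scr <- wilcoxon_screen(sep, meta)
  expect_equal(scr$p_value, 0.10)

  # identical groups: p = 1, FC = 1, not a candidate
  same <- dplyr::mutate(sep, adj_area = rep(5, 6))
  scr2 <- wilcoxon_screen(same, meta)
  expect_equal(scr2$p_value, 1)
  expect_equal(scr2$fold_change, 1)
  expect_false(scr2$candidate)

  # the FC gate blocks small shifts regardless of p
  n <- 30
  meta_big <- tibble::tibble(
    sample = sprintf("s%d", 1:(2 * n)),
    group = factor(rep(c("deficient", "normal"), each = n), c("deficient", "normal"))
  )
  small_shift <- tibble::tibble(
    sample = meta_big$sample, species = "y", lipid_class = "PC",
    adj_area = c(seq(1.19, 1.21, length.out = n), seq(0.99, 1.01, length.out = n))
  )
  scr3 <- wilcoxon_screen(small_shift, meta_big)
  expect_lt(scr3$p_value, 0.001)
  expect_lt(scr3$fold_change, 1.3)
  expect_false(scr3$candidate)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    # q_(i) = min over j >= i of p_(j) * m / j, capped at 1
    sorted <- p[o]
    stepped <- rev(cummin(rev(sorted * m / seq_len(m))))
    q[o] <- pmin(stepped, 1)
    q
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(11)
  for (i in 1:50) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("shadow-feature selection separates signal from noise", {
  set.seed(19)
  n <- 40
  y <- factor(rep(c("a", "b"), each = n))
  x_noise <- matrix(stats::rnorm(2 * n * 30), 2 * n, 30)
  signal <- c(stats::rnorm(n, 0, 0.2) + log(2), stats::rnorm(n, 0, 0.2))
  x <- cbind(signal = signal, zerovar = rep(1, 2 * n), x_noise)
  colnames(x) <- c("signal", "zerovar", sprintf("n%02d", 1:30))
  res <- boruta_select(x, y, seed = 1, max_iter = 50)
  expect_equal(
    as.character(res$decision[res$feature == "signal"]), "confirmed"
  )
  expect_equal(
    as.character(res$decision[res$feature == "zerovar"]), "rejected"
  )
  # deterministic under a fixed seed
  res2 <- boruta_select(x, y, seed = 1, max_iter = 50)
  expect_identical(res, res2)
})

test_that("a planted two-fold shift is confirmed across seeds", {
  n <- 40
  confirmed <- vapply(1:20, function(s) {
    set.seed(100 + s)
    y <- factor(rep(c("a", "b"), each = n))
    x <- cbind(
      planted = c(stats::rnorm(n, log(2), 0.2), stats::rnorm(n, 0, 0.2)),
      matrix(stats::rnorm(2 * n * 30, 0, 0.2), 2 * n, 30)
    )
    res <- boruta_select(x, y, seed = s, max_iter = 30)
    as.character(res$decision[res$feature == "planted"]) == "confirmed"
  }, logical(1))
  expect_gte(mean(confirmed), 0.95)
})

test_that("pure-noise matrices confirm nothing in most seeds", {
  n <- 30
  n_conf <- vapply(1:20, function(s) {
    set.seed(200 + s)
    y <- factor(rep(c("a", "b"), each = n))
    x <- matrix(stats::rnorm(2 * n * 20), 2 * n, 20)
    res <- boruta_select(x, y, seed = s, max_iter = 25)
    sum(res$decision == "confirmed")
  }, numeric(1))
  expect_gte(mean(n_conf == 0), 0.9)
})

test_that("abundance shares sum to one at both levels", {
  one <- abundance_shares(tibble::tibble(species = "a", isomer = "a/1", area = 7))
  expect_equal(one$species_share, 1)
  expect_equal(one$isomer_share, 1)

  two <- abundance_shares(tibble::tibble(
    species = "TAG 52:2", isomer = c("FA18:1", "FA16:0"), area = c(52.4, 47.6)
  ))
  expect_equal(two$isomer_share, c(0.524, 0.476))

  set.seed(29)
  many <- abundance_shares(tidyr::expand_grid(
    species = sprintf("sp%02d", 1:20), isomer = c("i1", "i2", "i3")
  ) |> dplyr::mutate(area = stats::runif(60)))
  expect_equal(
    sum(dplyr::distinct(many, species, species_share)$species_share), 1,
    tolerance = 1e-12
  )
  isomer_sums <- many |>
    dplyr::group_by(species) |>
    dplyr::summarise(s = sum(isomer_share), .groups = "drop")
  expect_equal(isomer_sums$s, rep(1, 20), tolerance = 1e-12)
  expect_error(abundance_shares(tibble::tibble(species = "a", isomer = "i", area = 0)), "zero")
})

test_that("synthetic cohorts are reproducible and realise their design", {
  des <- cohort_design(n_deficient = 40, n_normal = 40, n_species = 100,
                       n_planted = 4, missing_rate = 0)
  c1 <- generate_cohort(des, seed = 8)
  c2 <- generate_cohort(des, seed = 8)
  expect_identical(c1$areas, c2$areas)
  expect_identical(c1$planted, c2$planted)

  # planted fold changes are realised within 10% at n = 40 per group
  joined <- c1$areas |>
    dplyr::left_join(c1$meta, by = "sample") |>
    dplyr::filter(species %in% c1$planted$species) |>
    dplyr::group_by(species, group) |>
    dplyr::summarise(m = exp(mean(log(area))), .groups = "drop") |>
    tidyr::pivot_wider(names_from = group, values_from = m) |>
    dplyr::mutate(realised = deficient / normal) |>
    dplyr::left_join(c1$planted, by = "species")
  expect_true(all(abs(joined$realised / joined$fold_change - 1) < 0.10))

  # zero-effect designs leave the two groups exchangeable
  null <- generate_cohort(
    cohort_design(n_deficient = 40, n_normal = 40, n_species = 50,
                  n_planted = 0, n_batches = 1, missing_rate = 0),
    seed = 9
  )
  dat <- dplyr::left_join(null$areas, null$meta, by = "sample")
  sp <- unique(dat$species)[1:10]
  pooled <- dat |>
    dplyr::filter(species %in% sp) |>
    dplyr::group_by(species) |>
    dplyr::mutate(z = scale(log(area))[, 1]) |>
    dplyr::ungroup()
  ks <- suppressWarnings(stats::ks.test(
    pooled$z[pooled$group == "deficient"],
    pooled$z[pooled$group == "normal"]
  ))
  expect_gt(ks$p.value, 0.01)
})

test_that("the full pipeline recovers planted effects on a small cohort", {
  # classes must stay large enough that planting a few 2-fold effects leaves
  # the class totals (and hence the sum-normalized co-members) nearly intact
  des <- cohort_design(
    n_deficient = 30, n_normal = 30, n_species = 300, n_planted = 6,
    planted_fc_range = c(1.8, 2.5)
  )
  coh <- generate_cohort(des, seed = 21)
  res <- run_differential_pipeline(coh, seed = 21)
  expect_s3_class(res, "lipid_de")
  conf <- res$species[res$decision == "confirmed"]
  expect_gte(sum(coh$planted$species %in% conf), 5)
  # at 30 samples per group the occasional chance-correlated species survives
  # selection; the acceptance-scale cohort (46+ per group) is tested separately
  expect_lte(sum(!conf %in% coh$planted$species), 2)
  g <- glance(res)
  expect_equal(g$n_species, 300)
  expect_true(all(res$q_value >= 0 & res$q_value <= 1))
})
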