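# Two-group differential screening: filtering, imputation, class-sum
# normalization, empirical-Bayes batch adjustment, Wilcoxon + fold-change
# screening, Benjamini-Hochberg adjustment and shadow-feature random-forest
# selection.

#' Filter, impute and class-sum normalize a cohort table
#'
#' Species with missing values in `missing_sample_cutoff` or more samples are
#' removed; remaining missing values are imputed with the species median
#' across all samples; each species' area is then divided by its lipid-class
#' total within the sample (`norm_area`).
#'
#' @param areas Long tibble with columns `sample`, `species`, `lipid_class`,
#'   `area` (`NA` = missing).
#' @param missing_sample_cutoff Species missing in at least this many samples
#'   are dropped (default 10).
#' @return Tibble like `areas` with imputed `area` and added `norm_area`.
#' @export
preprocess <- function(areas, missing_sample_cutoff = 10) {
  keep <- areas |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_missing = sum(is.na(.data$area)), n = dplyr::n(), .groups = "drop")
  if (any(keep$n_missing == keep$n)) {
    stop("species with all values missing: ",
      paste(utils::head(keep$species[keep$n_missing == keep$n], 5), collapse = ", "),
      call. = FALSE
    )
  }
  kept <- keep$species[keep$n_missing < missing_sample_cutoff]
  areas |>
    dplyr::filter(.data$species %in% kept) |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(area = ifelse(
      is.na(.data$area),
      stats::median(.data$area, na.rm = TRUE),
      .data$area
    )) |>
    dplyr::group_by(.data$sample, .data$lipid_class) |>
    dplyr::mutate(norm_area = .data$area / sum(.data$area)) |>
    dplyr::ungroup()
}

#' Empirical-Bayes (ComBat-style) batch adjustment
#'
#' Parametric location/scale batch adjustment: per-feature batch means and
#' variances are estimated on data standardized under a model that preserves
#' the biological covariates, shrunk across features towards their priors
#' (normal prior on locations, inverse-gamma on scales) and removed.
#'
#' @param x Numeric matrix, features x samples.
#' @param batch Factor (or vector) of batch labels, one per sample; every
#'   batch needs >= 2 samples.
#' @param design Optional model matrix (samples x covariates, no intercept)
#'   of biological effects to preserve, e.g. group and sex indicators.
#' @param tol,max_iter Convergence control of the per-feature EB iterations.
#' @return Adjusted matrix with the same dimensions.
#' @export
combat_adjust <- function(x, batch, design = NULL, tol = 1e-6, max_iter = 100) {
  x <- as.matrix(x)
  batch <- droplevels(as.factor(batch))
  k <- nlevels(batch)
  n <- ncol(x)
  if (k < 2) stop("need >= 2 batches", call. = FALSE)
  if (any(table(batch) < 2)) stop("every batch needs >= 2 samples", call. = FALSE)
  batchmod <- stats::model.matrix(~ -1 + batch)
  if (!is.null(design)) {
    design <- as.matrix(design)
    conf <- apply(design, 2, function(col) {
      qr(cbind(batchmod, col))$rank <= qr(batchmod)$rank
    })
    if (any(conf)) {
      stop("covariate(s) confounded with batch", call. = FALSE)
    }
  }
  X <- cbind(batchmod, design)
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank (batch confounded with a covariate?)", call. = FALSE)

  n_batches <- as.vector(table(batch))
  B_hat <- solve(crossprod(X), crossprod(X, t(x)))
  grand_mean <- crossprod(n_batches / n, B_hat[seq_len(k), , drop = FALSE])
  var_pooled <- rowMeans((x - t(X %*% B_hat))^2)
  var_pooled[var_pooled == 0] <- .Machine$double.eps

  stand_mean <- t(matrix(grand_mean, nrow = n, ncol = nrow(x), byrow = TRUE))
  if (!is.null(design)) {
    stand_mean <- stand_mean + t(X[, -seq_len(k), drop = FALSE] %*% B_hat[-seq_len(k), , drop = FALSE])
  }
  z <- (x - stand_mean) / sqrt(var_pooled)

  adj <- z
  for (b in levels(batch)) {
    idx <- which(batch == b)
    nb <- length(idx)
    zb <- z[, idx, drop = FALSE]
    gamma_hat <- rowMeans(zb)
    delta_hat <- apply(zb, 1, stats::var)
    gamma_bar <- mean(gamma_hat)
    tau2 <- stats::var(gamma_hat)
    m <- mean(delta_hat)
    s2 <- stats::var(delta_hat)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2

    gamma_star <- gamma_hat
    delta_star <- delta_hat
    change <- 1
    iter <- 0
    while (change > tol && iter < max_iter) {
      gamma_new <- (tau2 * nb * gamma_hat + delta_star * gamma_bar) /
        (tau2 * nb + delta_star)
      sum2 <- rowSums((zb - gamma_new)^2)
      delta_new <- (0.5 * sum2 + b_prior) / (nb / 2 + a_prior - 1)
      change <- max(
        abs(gamma_new - gamma_star) / abs(gamma_star + 1e-12),
        abs(delta_new - delta_star) / abs(delta_star + 1e-12)
      )
      gamma_star <- gamma_new
      delta_star <- delta_new
      iter <- iter + 1
    }
    adj[, idx] <- (zb - gamma_star) / sqrt(delta_star)
  }
  adj * sqrt(var_pooled) + stand_mean
}

#' Batch adjustment on a long cohort table
#'
#' Applies [combat_adjust()] to log-transformed normalized areas, preserving
#' the group (and optionally sex) effect, and returns the table with an
#' `adj_area` column on the original scale.
#'
#' @param areas Long tibble with `sample`, `species`, `norm_area` columns
#'   (see [preprocess()]).
#' @param meta Sample metadata with `sample`, `batch`, `group` and optionally
#'   `sex`.
#' @param value Column to adjust (default `"norm_area"`).
#' @return `areas` with an `adj_area` column added.
#' @export
batch_adjust <- function(areas, meta, value = "norm_area") {
  wide <- areas |>
    dplyr::select("sample", "species", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "sample", values_from = dplyr::all_of(value))
  mat <- log(as.matrix(wide[, -1]) + 1e-12)
  meta <- meta[match(colnames(mat), meta$sample), ]
  covars <- stats::model.matrix(~group, data = meta)[, -1, drop = FALSE]
  if ("sex" %in% names(meta)) {
    covars <- cbind(covars, stats::model.matrix(~sex, data = meta)[, -1, drop = FALSE])
  }
  adj <- combat_adjust(mat, meta$batch, covars)
  long <- tibble::as_tibble(exp(adj)) |>
    dplyr::mutate(species = wide$species) |>
    tidyr::pivot_longer(-"species", names_to = "sample", values_to = "adj_area")
  dplyr::left_join(areas, long, by = c("sample", "species"))
}

#' Wilcoxon + fold-change screen
#'
#' Per species: the fold change between group means (deficient over normal)
#' and the two-sided Wilcoxon rank-sum p-value. The exact null distribution
#' is used when the combined sample size is <= 20 and there are no ties;
#' otherwise the normal approximation with tie correction. A species is a
#' candidate when `FC > fc_threshold` or `FC < 1 / fc_threshold` and
#' `p < p_threshold`.
#'
#' @param areas Long tibble with `sample`, `species`, and a value column.
#' @param meta Metadata with `sample` and `group` (two levels; the first
#'   level is the numerator of the fold change).
#' @param value Value column (default `"adj_area"`).
#' @param fc_threshold,p_threshold Screen thresholds (defaults 1.3, 0.05).
#' @param fc_method `"mean"` (default) or `"median"` group summary.
#' @return Tibble per species: `fold_change`, `p_value`, `candidate`.
#' @export
wilcoxon_screen <- function(areas, meta, value = "adj_area",
                            fc_threshold = 1.3, p_threshold = 0.05,
                            fc_method = c("mean", "median")) {
  fc_method <- match.arg(fc_method)
  groups <- unique(as.character(meta$group))
  if (length(groups) != 2) stop("exactly two groups are required", call. = FALSE)
  g <- stats::setNames(as.character(meta$group), meta$sample)
  summ <- if (fc_method == "mean") mean else stats::median
  areas |>
    dplyr::group_by(.data$species, dplyr::across(dplyr::any_of("lipid_class"))) |>
    dplyr::reframe(
      {
        v <- .data[[value]]
        grp <- g[.data$sample]
        x <- v[grp == groups[1]]
        y <- v[grp == groups[2]]
        fc <- summ(x) / summ(y)
        p <- if (all(v == v[1])) {
          1
        } else {
          exact <- (length(x) + length(y)) <= 20 && !any(duplicated(v))
          suppressWarnings(
            stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
          )
        }
        tibble::tibble(fold_change = fc, p_value = p)
      }
    ) |>
    dplyr::mutate(
      candidate = (.data$fold_change > fc_threshold |
        .data$fold_change < 1 / fc_threshold) &
        .data$p_value < p_threshold
    )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (`stats::p.adjust`'s BH method).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (!all(p >= 0 & p <= 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Shadow-feature random-forest selection
#'
#' Boruta-style wrapper selection: each iteration appends a shuffled
#' ("shadow") copy of every feature, fits a random forest and scores a hit
#' for every real feature whose impurity importance beats the best shadow
#' importance. Features are confirmed (rejected) once a two-sided binomial
#' test on their hit count against chance (probability 1/2) becomes
#' significant; the level is Bonferroni-adjusted across features (as in the
#' reference implementation of the algorithm), so chance correlations rarely
#' survive. Undecided features are tentative after `max_iter` iterations.
#' Deterministic under a fixed seed.
#'
#' @param x Data frame or matrix of features (samples x features).
#' @param y Two-level factor of group labels.
#' @param seed Integer seed.
#' @param max_iter Maximum iterations (default 100).
#' @param num_trees Trees per forest (default 100).
#' @param alpha Two-sided significance level of the binomial decisions
#'   (default 0.01).
#' @return Tibble per feature: `hits`, `n_iter`, `decision`
#'   (`confirmed` / `rejected` / `tentative`).
#' @export
boruta_select <- function(x, y, seed = 1, max_iter = 100, num_trees = 100,
                          alpha = 0.01) {
  x <- as.data.frame(x)
  y <- as.factor(y)
  stopifnot(nlevels(y) == 2, ncol(x) >= 2)
  if (min(table(y)) < 2) stop("need >= 2 samples per group", call. = FALSE)
  p <- ncol(x)
  feat_names <- colnames(x)
  colnames(x) <- paste0("f", seq_len(p))

  .with_seed(seed, {
    hits <- integer(p)
    n_iter <- integer(p)
    decision <- rep("tentative", p)
    for (it in seq_len(max_iter)) {
      und <- decision == "tentative"
      if (!any(und)) break
      shadow <- as.data.frame(lapply(x, sample))
      colnames(shadow) <- paste0("s", seq_len(p))
      dat <- cbind(x, shadow)
      fit <- ranger::ranger(
        x = dat, y = y,
        num.trees = num_trees,
        importance = "impurity",
        seed = seed + it,
        num.threads = 1
      )
      imp <- fit$variable.importance
      shadow_max <- max(imp[paste0("s", seq_len(p))])
      real_imp <- imp[paste0("f", seq_len(p))]
      hits[und] <- hits[und] + (real_imp[und] > shadow_max)
      n_iter[und] <- n_iter[und] + 1L
      cut <- alpha / 2 / p # two-sided, Bonferroni across features
      for (j in which(und)) {
        p_hi <- stats::pbinom(hits[j] - 1, n_iter[j], 0.5, lower.tail = FALSE)
        p_lo <- stats::pbinom(hits[j], n_iter[j], 0.5)
        if (p_hi < cut) decision[j] <- "confirmed"
        if (p_lo < cut) decision[j] <- "rejected"
      }
    }
    tibble::tibble(
      feature = feat_names,
      hits = hits,
      n_iter = n_iter,
      decision = factor(decision, levels = c("confirmed", "tentative", "rejected"))
    )
  })
}

#' Species and isomer abundance shares
#'
#' @param areas Tibble with columns `species`, `isomer` and `area`.
#' @return `areas` with `species_share` (species total over grand total) and
#'   `isomer_share` (isomer area over its species total) added; shares sum
#'   to 1 at each level.
#' @export
abundance_shares <- function(areas) {
  total <- sum(areas$area)
  if (total == 0) stop("grand total area is zero", call. = FALSE)
  areas |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(
      species_total = sum(.data$area),
      isomer_share = .data$area / .data$species_total
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(species_share = .data$species_total / total) |>
    dplyr::select(-"species_total")
}

#' Run the full differential pipeline
#'
#' [preprocess()] -> [batch_adjust()] -> [wilcoxon_screen()] ->
#' [bh_adjust()] -> [boruta_select()] on the screened candidates.
#'
#' @param cohort A `lipid_cohort` (see [generate_cohort()]) or a list with
#'   `areas` and `meta` tibbles.
#' @param seed Integer seed (drives the forest selection).
#' @param missing_sample_cutoff,fc_threshold,p_threshold,fc_method,max_iter,num_trees,alpha
#'   Stage parameters, see the stage functions.
#' @return A `lipid_de` tibble per species: `fold_change`, `p_value`,
#'   `q_value`, `candidate`, `decision`.
#' @export
run_differential_pipeline <- function(cohort, seed = 1,
                                      missing_sample_cutoff = 10,
                                      fc_threshold = 1.3, p_threshold = 0.05,
                                      fc_method = "mean",
                                      max_iter = 100, num_trees = 100,
                                      alpha = 0.01) {
  pre <- preprocess(cohort$areas, missing_sample_cutoff)
  adj <- batch_adjust(pre, cohort$meta)
  scr <- wilcoxon_screen(
    adj, cohort$meta,
    fc_threshold = fc_threshold, p_threshold = p_threshold,
    fc_method = fc_method
  )
  scr$q_value <- bh_adjust(scr$p_value)

  cand <- scr$species[scr$candidate]
  scr$decision <- factor("not_screened", levels = c("confirmed", "tentative", "rejected", "not_screened"))
  if (length(cand) >= 2) {
    wide <- adj |>
      dplyr::filter(.data$species %in% cand) |>
      dplyr::select("sample", "species", "adj_area") |>
      tidyr::pivot_wider(names_from = "species", values_from = "adj_area")
    x <- as.data.frame(wide[, -1])
    y <- cohort$meta$group[match(wide$sample, cohort$meta$sample)]
    bor <- boruta_select(
      x, y,
      seed = seed, max_iter = max_iter,
      num_trees = num_trees, alpha = alpha
    )
    scr$decision[match(bor$feature, scr$species)] <- as.character(bor$decision)
  }
  class(scr) <- c("lipid_de", class(scr))
  attr(scr, "n_candidates") <- length(cand)
  scr
}
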