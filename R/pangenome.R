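#' Partition an ortholog table into core, accessory and singleton families
#'
#' With G genomes: core families have occupancy G, accessory families
#' occupancy 2..G-1, singletons occupancy 1. The partition is exhaustive:
#' `pan == core + accessory + singleton`.
#'
#' @param table An `ortholog_table`.
#' @return One-row tibble: `pan`, `core`, `accessory`, `singleton`,
#'   `n_genomes`.
#' @export
partition_counts <- function(table) {
  stopifnot(inherits(table, "ortholog_table"))
  G <- length(attr(table, "genomes"))
  occ <- table$occupancy
  tibble(
    pan = length(occ),
    core = sum(occ == G),
    accessory = sum(occ >= 2 & occ <= G - 1),
    singleton = sum(occ == 1),
    n_genomes = G
  )
}

#' Pan/core development curve by genome subsampling
#'
#' For every subset size N in 1..G, genome subsets are drawn and the pan
#' size (families present in at least one subset genome) and core size
#' (families present in every subset genome) are recorded. When
#' `choose(G, N) <= max_samples_per_n` all subsets are enumerated;
#' otherwise `max_samples_per_n` distinct subsets are sampled uniformly.
#' Seeded and reproducible.
#'
#' @param table An `ortholog_table`.
#' @param max_samples_per_n Sampling cap per subset size (default 500).
#' @param seed RNG seed for the sampled sizes.
#' @return A `development_curve`: tibble with columns `n` (subset size),
#'   `subset_id`, `genomes` (comma-joined subset members), `pan`, `core`
#'   and attributes `n_genomes`, `exhaustive` (logical per N), `seed`.
#' @export
pan_development <- function(table, max_samples_per_n = 500, seed = 1) {
  stopifnot(inherits(table, "ortholog_table"), max_samples_per_n >= 1)
  P <- presence_matrix(table)
  G <- ncol(P)
  if (G < 2) abort("need at least two genomes for a development curve")
  with_local_seed(seed, {
    rows <- vector("list", G)
    exhaustive <- logical(G)
    for (N in seq_len(G)) {
      n_total <- choose(G, N)
      if (n_total <= max_samples_per_n) {
        subsets <- utils::combn(G, N, simplify = FALSE)
        exhaustive[N] <- TRUE
      } else {
        subsets <- sample_distinct_subsets(G, N, max_samples_per_n)
        exhaustive[N] <- FALSE
      }
      pan <- integer(length(subsets)); core <- integer(length(subsets))
      members <- character(length(subsets))
      for (i in seq_along(subsets)) {
        hits <- rowSums(P[, subsets[[i]], drop = FALSE])
        pan[i] <- sum(hits > 0)
        core[i] <- sum(hits == N)
        members[i] <- paste(colnames(P)[subsets[[i]]], collapse = ",")
      }
      rows[[N]] <- tibble(n = N, subset_id = seq_along(subsets),
                          genomes = members, pan = pan, core = core)
    }
    out <- bind_rows(rows)
    attr(out, "n_genomes") <- G
    attr(out, "exhaustive") <- exhaustive
    attr(out, "seed") <- seed
    class(out) <- c("development_curve", class(out))
    out
  })
}

# uniform distinct subsets of size N from 1..G by rejection
sample_distinct_subsets <- function(G, N, n_wanted) {
  seen <- new.env(parent = emptyenv())
  out <- vector("list", n_wanted)
  got <- 0L
  while (got < n_wanted) {
    s <- sort(sample.int(G, N))
    key <- paste(s, collapse = ",")
    if (!exists(key, envir = seen)) {
      assign(key, TRUE, envir = seen)
      got <- got + 1L
      out[[got]] <- s
    }
  }
  out
}

#' Per-N medians and quartiles of a development curve
#'
#' The median of an even number of samples is the mean of the two central
#' values; quartiles are `stats::quantile` type 7.
#'
#' @param curve A `development_curve`.
#' @return Tibble: `n`, `pan_median`, `pan_q1`, `pan_q3`, `core_median`,
#'   `core_q1`, `core_q3`, `n_subsets`.
#' @export
development_medians <- function(curve) {
  stopifnot(inherits(curve, "development_curve"))
  curve |>
    as_tibble() |>
    group_by(.data$n) |>
    summarise(
      pan_median = median(.data$pan),
      pan_q1 = quantile(.data$pan, 0.25, names = FALSE),
      pan_q3 = quantile(.data$pan, 0.75, names = FALSE),
      core_median = median(.data$core),
      core_q1 = quantile(.data$core, 0.25, names = FALSE),
      core_q3 = quantile(.data$core, 0.75, names = FALSE),
      n_subsets = dplyr::n(),
      .groups = "drop"
    )
}

fit_input <- function(x, value_col) {
  if (inherits(x, "development_curve")) {
    med <- development_medians(x)
    tibble(n = med$n, value = med[[paste0(value_col, "_median")]])
  } else if (is.data.frame(x)) {
    nm <- names(x)
    vc <- if (value_col %in% nm) value_col else
      if ("value" %in% nm) "value" else
        abort(paste0("data frame needs columns 'n' and '", value_col,
                     "' (or 'value')"))
    stopifnot("n" %in% nm)
    tibble(n = x$n, value = x[[vc]])
  } else {
    abort("expected a development_curve or a data frame")
  }
}

#' Fit Heaps' law to pan-genome medians
#'
#' Nonlinear least squares of the power law `n_genes = k * N^gamma` against
#' the median pan sizes, on the original scale, initialized from a log-log
#' ordinary least squares fit. The openness exponent is `alpha = 1 - gamma`:
#' `alpha < 1` signifies an open pangenome. Flat input (all medians equal)
#' has the closed-form solution `k = median value, gamma = 0`.
#'
#' @param x A `development_curve`, or a data frame with columns `n` and
#'   `pan` (or `value`).
#' @return A `heaps_fit` with elements `k`, `gamma`, `alpha`,
#'   `residual_ss`, `data`, `converged`. Supports [tidy()], [glance()] and
#'   `predict`.
#' @export
#' @examples
#' fit_heaps(data.frame(n = 1:8, pan = 2092 * (1:8)^0.185))
fit_heaps <- function(x) {
  d <- fit_input(x, "pan")
  d <- d[!is.na(d$value), ]
  if (length(unique(d$n)) < 3) abort("need medians at >= 3 distinct N")
  if (any(d$value <= 0)) abort("pan sizes must be positive to fit Heaps' law")
  if (diff(range(d$value)) == 0) {
    k <- d$value[1]; gamma <- 0
  } else {
    init <- stats::lm(log(value) ~ log(n), data = d)
    start <- list(k = exp(coef(init)[[1]]), gamma = coef(init)[[2]])
    fit <- tryCatch(
      minpack.lm::nlsLM(value ~ k * n^gamma, data = d, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) abort(paste0("Heaps fit did not converge: ",
                                       conditionMessage(e))))
    k <- coef(fit)[["k"]]; gamma <- coef(fit)[["gamma"]]
  }
  resid <- d$value - k * d$n^gamma
  structure(list(k = k, gamma = gamma, alpha = 1 - gamma,
                 residual_ss = sum(resid^2), data = d,
                 converged = TRUE),
            class = "heaps_fit")
}

#' Fit an exponential decay to core-genome medians
#'
#' Nonlinear least squares of `n_genes = k * exp(-N / tau) + tg_theta`
#' against the median core sizes. Initialization: `tg_theta` = smallest
#' median, `k` = range of the medians, `tau` = G/3. `tau` is constrained
#' positive and `tg_theta` non-negative. Flat input short-circuits to
#' `k = 0, tg_theta = median value`.
#'
#' @param x A `development_curve`, or a data frame with columns `n` and
#'   `core` (or `value`).
#' @return A `decay_fit` with elements `k`, `tau`, `tg_theta`,
#'   `residual_ss`, `data`, `converged`.
#' @export
#' @examples
#' fit_decay(data.frame(n = 1:8, core = 670 * exp(-(1:8) / 4.8) + 1384))
fit_decay <- function(x) {
  d <- fit_input(x, "core")
  d <- d[!is.na(d$value), ]
  if (length(unique(d$n)) < 4) abort("need medians at >= 4 distinct N")
  G <- max(d$n)
  if (diff(range(d$value)) == 0) {
    k <- 0; tau <- G / 3; tg_theta <- d$value[1]
  } else {
    start <- list(k = max(d$value) - min(d$value), tau = G / 3,
                  tg_theta = min(d$value))
    fit <- tryCatch(
      minpack.lm::nlsLM(value ~ k * exp(-n / tau) + tg_theta, data = d,
                        start = start,
                        lower = c(k = -Inf, tau = 1e-9, tg_theta = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) abort(paste0("decay fit did not converge: ",
                                       conditionMessage(e))))
    k <- coef(fit)[["k"]]; tau <- coef(fit)[["tau"]]
    tg_theta <- coef(fit)[["tg_theta"]]
  }
  resid <- d$value - (k * exp(-d$n / tau) + tg_theta)
  structure(list(k = k, tau = tau, tg_theta = tg_theta,
                 residual_ss = sum(resid^2), data = d, converged = TRUE),
            class = "decay_fit")
}

#' Classify pangenome openness from a Heaps fit
#'
#' `alpha < 1` means the pangenome keeps growing with added genomes
#' ("open"); `alpha >= 1` (boundary included) is "closed".
#'
#' @param fit A `heaps_fit`.
#' @return `"open"` or `"closed"`.
#' @export
classify_openness <- function(fit) {
  stopifnot(inherits(fit, "heaps_fit"))
  if (fit$alpha < 1) "open" else "closed"
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("Heaps' law fit: n = %.3f * N^%.3f  (alpha = %.3f, %s pangenome)\n",
              x$k, x$gamma, x$alpha, classify_openness(x)))
  cat(sprintf("  residual SS %.4g over %d points\n",
              x$residual_ss, nrow(x$data)))
  invisible(x)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Core-genome decay fit: n = %.3f * exp(-N/%.3f) + %.3f\n",
              x$k, x$tau, x$tg_theta))
  cat(sprintf("  residual SS %.4g over %d points\n",
              x$residual_ss, nrow(x$data)))
  invisible(x)
}

#' @export
predict.heaps_fit <- function(object, newdata = NULL, ...) {
  n <- if (is.null(newdata)) object$data$n else
    if (is.data.frame(newdata)) newdata$n else newdata
  object$k * n^object$gamma
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  n <- if (is.null(newdata)) object$data$n else
    if (is.data.frame(newdata)) newdata$n else newdata
  object$k * exp(-n / object$tau) + object$tg_theta
}

#' @export
tidy.heaps_fit <- function(x, ...) {
  tibble(term = c("k", "gamma", "alpha"),
         estimate = c(x$k, x$gamma, x$alpha))
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("k", "tau", "tg_theta"),
         estimate = c(x$k, x$tau, x$tg_theta))
}

#' @export
glance.heaps_fit <- function(x, ...) {
  tibble(residual_ss = x$residual_ss, n_points = nrow(x$data),
         openness = classify_openness(x), converged = x$converged)
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble(residual_ss = x$residual_ss, n_points = nrow(x$data),
         converged = x$converged)
}

#' Plot a development curve
#'
#' Two panels mirroring the conventional pangenome figure: pan-genome and
#' core-genome sizes against the number of sampled genomes, with per-N
#' sample spread and the median line; optional fitted curves are overlaid.
#'
#' @param object A `development_curve`.
#' @param heaps,decay Optional `heaps_fit` / `decay_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.development_curve <- function(object, heaps = NULL, decay = NULL,
                                       ...) {
  long <- object |>
    as_tibble() |>
    tidyr::pivot_longer(c("pan", "core"), names_to = "component",
                        values_to = "size") |>
    mutate(component = factor(.data$component, c("pan", "core"),
                              c("pan genome", "core genome")))
  med <- long |>
    group_by(.data$n, .data$component) |>
    summarise(size = median(.data$size), .groups = "drop")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$size)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.25, size = 0.8) +
    ggplot2::geom_line(data = med, colour = "steelblue", linewidth = 1) +
    ggplot2::geom_point(data = med, colour = "steelblue", size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "genomes sampled (N)", y = "gene families (n)") +
    ggplot2::theme_bw()
  grid <- tibble(n = seq(1, attr(object, "n_genomes"), length.out = 100))
  if (!is.null(heaps)) {
    p <- p + ggplot2::geom_line(
      data = mutate(grid, size = predict(heaps, grid),
                    component = factor("pan genome",
                                       c("pan genome", "core genome"))),
      colour = "firebrick", linetype = 2)
  }
  if (!is.null(decay)) {
    p <- p + ggplot2::geom_line(
      data = mutate(grid, size = predict(decay, grid),
                    component = factor("core genome",
                                       c("pan genome", "core genome"))),
      colour = "firebrick", linetype = 2)
  }
  p
}

#' Write a development curve (and medians) as TSV
#' @param curve A `development_curve`.
#' @param path Output path for the samples table.
#' @param medians_path Optional path for the per-N medians table.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curve, path, medians_path = NULL) {
  readr::write_tsv(as_tibble(curve), path)
  if (!is.null(medians_path)) {
    readr::write_tsv(development_medians(curve), medians_path)
  }
  invisible(path)
}
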