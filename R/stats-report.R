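#' One-way ANOVA with Tukey HSD and compact-letter display
#'
#' Tests whether group means differ (one-way ANOVA), follows up with Tukey's
#' honestly-significant-difference pairwise comparisons at level `alpha`,
#' and summarizes the pairwise decisions as a compact-letter display:
#' groups sharing a letter are not significantly different. Letters are
#' assigned by the greedy insert-and-absorb algorithm with groups ordered by
#' descending mean, so `"a"` always contains the highest-mean group.
#'
#' The degenerate case of zero residual variance is handled directly: pairs
#' with equal means are declared not different, pairs with unequal means
#' different (so identical groups all share one letter).
#'
#' @param x A named list of numeric vectors (one per group), or a data frame
#'   with columns `value` and `group`. At least two groups with at least two
#'   observations each.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `anova_cld`: list with `f_statistic`,
#'   `p_value`, `alpha`, `pairwise` (data frame of Tukey-adjusted pairwise
#'   decisions) and `summary` (data frame with `group`, `mean`, `sd`, `n`,
#'   `letter`, ordered by descending mean).
#' @examples
#' set.seed(1)
#' anova_tukey(list(low = rnorm(10), also_low = rnorm(10),
#'                  high = rnorm(10, 10)))
#' @export
anova_tukey <- function(x, alpha = 0.05) {
  if (is.data.frame(x)) {
    stopifnot(all(c("value", "group") %in% names(x)))
    groups <- split(x$value, x$group)
  } else groups <- x
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  n_per <- lengths(groups)
  if (any(n_per < 2))
    stop("every group needs at least two observations (",
         paste(names(groups)[n_per < 2], collapse = ", "), ")",
         call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))

  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), n_per), levels = names(groups)))
  means <- vapply(groups, mean, 0)
  sds <- vapply(groups, stats::sd, 0)

  fit <- stats::aov(value ~ group, data = df)
  anova_tab <- summary(fit)[[1]]
  mse <- anova_tab["Residuals", "Mean Sq"]

  labels <- names(groups)
  pairs <- utils::combn(labels, 2)
  if (mse > 0) {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    # TukeyHSD labels pairs "b-a"; rebuild in our order
    key <- function(a, b) {
      k1 <- paste(b, a, sep = "-"); k2 <- paste(a, b, sep = "-")
      if (k1 %in% rownames(tk)) k1 else k2
    }
    p_adj <- vapply(seq_len(ncol(pairs)), function(j)
      tk[key(pairs[1, j], pairs[2, j]), "p adj"], 0)
    signif <- p_adj < alpha
  } else {
    p_adj <- ifelse(means[pairs[1, ]] == means[pairs[2, ]], 1, 0)
    signif <- p_adj < alpha
  }
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         diff = means[pairs[1, ]] - means[pairs[2, ]],
                         p_adj = p_adj, significant = signif,
                         row.names = NULL)

  letters_vec <- compact_letters(labels[order(-means)], {
    sig <- pairwise[pairwise$significant, c("group1", "group2"), drop = FALSE]
    sig
  })
  summary_df <- data.frame(group = labels, mean = unname(means),
                           sd = unname(sds), n = unname(n_per),
                           letter = unname(letters_vec[labels]),
                           row.names = NULL)
  summary_df <- summary_df[order(-summary_df$mean), ]
  structure(list(f_statistic = unname(anova_tab["group", "F value"]),
                 p_value = unname(anova_tab["group", "Pr(>F)"]),
                 alpha = alpha, pairwise = pairwise, summary = summary_df),
            class = "anova_cld")
}

# Greedy insert-and-absorb compact letter display.
# `ordered_groups`: group labels in display order (descending mean);
# `sig_pairs`: data frame of significantly different pairs.
compact_letters <- function(ordered_groups, sig_pairs) {
  cols <- list(ordered_groups)          # start: one column with all groups
  for (i in seq_len(nrow(sig_pairs))) {
    g1 <- sig_pairs$group1[i]; g2 <- sig_pairs$group2[i]
    j <- 1
    while (j <= length(cols)) {
      if (g1 %in% cols[[j]] && g2 %in% cols[[j]]) {
        # split the offending column into two, dropping one group each
        c1 <- setdiff(cols[[j]], g1)
        c2 <- setdiff(cols[[j]], g2)
        cols[[j]] <- c1
        cols[[length(cols) + 1]] <- c2
      }
      j <- j + 1
    }
    # absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] %in% cols[[b]]) &&
          (length(cols[[a]]) < length(cols[[b]]) || a > b)) keep[a] <- FALSE
    }
    cols <- cols[keep]
    cols <- cols[lengths(cols) > 0]
  }
  # order columns by the position of their best group; letter them
  best <- vapply(cols, function(cl) min(match(cl, ordered_groups)), 0)
  cols <- cols[order(best)]
  out <- stats::setNames(rep("", length(ordered_groups)), ordered_groups)
  for (j in seq_along(cols))
    out[cols[[j]]] <- paste0(out[cols[[j]]], letters[j])
  out
}

#' @export
print.anova_cld <- function(x, digits = 4, ...) {
  cat(sprintf("One-way ANOVA: F = %s, p = %s (Tukey HSD at alpha = %g)\n",
              format(x$f_statistic, digits = digits),
              format.pval(x$p_value, digits = digits), x$alpha))
  print(x$summary, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Run the full storage-study analysis pipeline
#'
#' End-to-end orchestration over synthetic (or file-based) inputs:
#' generates replicate kinetic series for the requested presets, fits the
#' appropriate model per replicate, aggregates replicates, attaches Tukey
#' compact letters comparing conditions within each analyte and parameter,
#' converts synthetic spectra to CIELAB colours and day-pair CIEDE2000
#' colour differences, and tabulates surfactant spectral shifts per pH.
#' All randomness derives from `seed`; rerunning with the same
#' configuration and seed reproduces every numeric cell exactly.
#'
#' @param config A list (or path to a JSON file) with optional elements
#'   `presets` (character vector of [kinetic_presets()] names; default all),
#'   `kinetic_csv` (path to a long-format CSV read via [read_kinetic_csv()]
#'   instead of simulation), `seed` (integer, default 1), `day_pair`
#'   (two days for the colour difference, default `c(0, 7)`), and `alpha`
#'   (default 0.05).
#' @param out_dir Optional directory: when given, writes
#'   `kinetic_parameters.csv`, `lab_colors.csv`, `spectral_shifts.csv` and
#'   `run_log.json` there.
#' @return An object of class `pigmentox_report`: list of the three tables
#'   plus the per-replicate fits and the effective config.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  day_pair <- config$day_pair %||% c(0, 7)
  alpha <- config$alpha %||% 0.05

  presets <- kinetic_presets(seed = seed)
  if (!is.null(config$presets)) {
    missing <- setdiff(config$presets, names(presets))
    if (length(missing))
      stop("simulation stage: unknown preset(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    presets <- presets[config$presets]
  }

  series <- if (!is.null(config$kinetic_csv)) {
    if (!file.exists(config$kinetic_csv))
      stop("input stage: kinetic_csv not found: ", config$kinetic_csv,
           call. = FALSE)
    read_kinetic_csv(config$kinetic_csv)
  } else {
    unlist(lapply(presets, gen_kinetic_series), recursive = FALSE)
  }

  use_sigmoid <- vapply(series, function(s)
    s$analyte %in% c("LOOH", "propanal", "hexanal"), TRUE)
  fits <- vector("list", length(series))
  for (i in seq_along(series)) {
    fits[[i]] <- if (use_sigmoid[i]) fit_sigmoid(series[[i]])
                 else fit_decay(series[[i]])
  }

  keys <- vapply(fits, condition_key, character(1))
  agg <- rbind_fill(lapply(split(fits, keys), function(fs) {
    if (length(fs) >= 2) aggregate_replicates(fs) else NULL
  }))
  rownames(agg) <- NULL

  # Tukey letters: compare conditions within each analyte, on the
  # per-replicate fitted rate constants
  agg$k_letter <- NA_character_
  for (an in unique(agg$analyte)) {
    idx <- which(vapply(fits, function(f) identical(f$analyte, an), TRUE))
    gs <- split(vapply(fits[idx], function(f) unname(stats::coef(f)["k"]), 0),
                keys[idx])
    gs <- gs[lengths(gs) >= 2]
    if (length(gs) >= 2) {
      cld <- anova_tukey(gs, alpha = alpha)
      agg_keys <- paste(agg$sample_id, vapply(agg$pH, format, ""),
                        vapply(agg$extract_dose, format, ""), agg$analyte,
                        sep = "|")
      for (r in seq_len(nrow(cld$summary))) {
        agg$k_letter[agg_keys == cld$summary$group[r]] <-
          cld$summary$letter[r]
      }
    }
  }
  kin_tab <- format_kinetic_table(agg)

  # colour table: synthetic spectra at the two days per decay condition
  ph_levels <- sort(unique(agg$pH[agg$model == "decay_fit"]))
  if (!length(ph_levels)) ph_levels <- c(2, 3, 4, 6)
  lab_rows <- lapply(ph_levels, function(ph) {
    labs <- lapply(day_pair, function(d)
      spectrum_to_lab(gen_spectrum(ph, with_sds = TRUE, day = d,
                                   seed = seed + round(100 * ph) + d)))
    de <- delta_e2000(labs[[1]], labs[[2]])
    data.frame(pH = ph, day1 = day_pair[1], day2 = day_pair[2],
               L1 = labs[[1]]$L, a1 = labs[[1]]$a, b1 = labs[[1]]$b,
               L2 = labs[[2]]$L, a2 = labs[[2]]$a, b2 = labs[[2]]$b,
               delta_e00 = de)
  })
  lab_tab <- do.call(rbind, lab_rows)

  shift_rows <- lapply(c(2, 3, 4, 6), function(ph) {
    sh <- spectral_shift(
      gen_spectrum(ph, with_sds = FALSE, day = 0, seed = seed + round(10 * ph)),
      gen_spectrum(ph, with_sds = TRUE, day = 0, seed = seed + round(10 * ph) + 1))
    data.frame(pH = ph, delta_nm = sh$delta_nm, kind = sh$kind,
               rel_abs_change_pct = sh$rel_abs_change)
  })
  shift_tab <- do.call(rbind, shift_rows)

  out <- structure(list(kinetic_parameters = kin_tab,
                        lab_colors = lab_tab,
                        spectral_shifts = shift_tab,
                        fits = fits,
                        config = list(seed = seed, day_pair = day_pair,
                                      alpha = alpha,
                                      presets = names(presets))),
                   class = "pigmentox_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(kin_tab, file.path(out_dir, "kinetic_parameters.csv"),
                     row.names = FALSE)
    utils::write.csv(lab_tab, file.path(out_dir, "lab_colors.csv"),
                     row.names = FALSE)
    utils::write.csv(shift_tab, file.path(out_dir, "spectral_shifts.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out$config, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# rbind data frames with differing columns, padding with NA
rbind_fill <- function(dfs) {
  dfs <- Filter(Negate(is.null), dfs)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (nm in setdiff(cols, names(d))) d[[nm]] <- NA
    d[cols]
  }))
}

format_kinetic_table <- function(agg) {
  fmt_pm <- function(m, s) ifelse(is.na(m), "—",
                                  sprintf("%.3g ± %.2g", m,
                                          ifelse(is.na(s), 0, s)))
  tab <- agg[, c("sample_id", "pH", "extract_dose", "analyte", "model", "n")]
  tab$k <- fmt_pm(agg$k_mean, agg$k_sd)
  if ("t_half_mean" %in% names(agg))
    tab$t_half <- fmt_pm(agg$t_half_mean, agg$t_half_sd)
  if ("t_ind_mean" %in% names(agg))
    tab$t_ind <- ifelse(!is.na(agg$n_ind) & agg$n_ind == 0, "—",
                        fmt_pm(agg$t_ind_mean, agg$t_ind_sd))
  if ("k_letter" %in% names(agg)) tab$k_letter <- agg$k_letter
  # keep the raw means alongside the formatted cells
  raw_cols <- grep("_mean$|_sd$|n_ind|t_half_from_mean_k", names(agg),
                   value = TRUE)
  cbind(tab, agg[, raw_cols, drop = FALSE])
}

#' @export
print.pigmentox_report <- function(x, ...) {
  cat("pigmentox pipeline report\n")
  cat(sprintf("  seed %d, alpha %g, colour day pair (%g, %g)\n",
              x$config$seed, x$config$alpha,
              x$config$day_pair[1], x$config$day_pair[2]))
  cat(sprintf("  %d replicate fits over %d conditions\n\n",
              length(x$fits), nrow(x$kinetic_parameters)))
  cat("Kinetic parameters (mean ± SD across replicates):\n")
  print(x$kinetic_parameters[, !grepl("_mean$|_sd$|n_ind|t_half_from",
                                      names(x$kinetic_parameters))],
        row.names = FALSE)
  cat("\nColour differences (CIEDE2000):\n")
  print(x$lab_colors[, c("pH", "day1", "day2", "delta_e00")],
        row.names = FALSE, digits = 4)
  cat("\nSurfactant spectral shifts:\n")
  print(x$spectral_shifts, row.names = FALSE, digits = 4)
  invisible(x)
}
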