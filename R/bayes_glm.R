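# Hierarchical Bayesian factorial models for beta power (frequency x
# modality x rhythmicity x electrode x participant, all interactions) and
# behavioural metrics (no electrode factor). Gaussian likelihood; each
# effect family's deflections share a zero-mean Gaussian prior with its own
# half-Gaussian-hyperpriored scale (hierarchical shrinkage); estimated by a
# blocked Gibbs sampler (see src/gibbs.cpp). Cue-condition posteriors are
# participant-averaged predicted cell values, which are invariant to
# sum-to-zero recentring; recentred deflections are recovered from them on
# demand.

factor_letter_map <- c(F = "frequency", M = "modality", R = "rhythmicity",
                       E = "electrode", P = "participant")

design_levels <- function(table) {
  lv <- list(
    F = c("1Hz", "3Hz"), M = c("AUD", "VIS"), R = c("ISO", "POLY")
  )
  if ("electrode" %in% names(table)) lv$E <- unique(table$electrode)
  lv$P <- unique(table$participant)
  lv
}

#' Build the factorial design for a cell table
#'
#' Expands every non-empty subset of the factors (frequency, modality,
#' rhythmicity, participant, and electrode when present) into an effect
#' family and maps each observation to its level within each family.
#'
#' @param table data.frame with columns participant, frequency, modality,
#'   rhythmicity, optionally electrode, and value.
#' @return A list of class `factor_design`: `idx` (observations x families),
#'   `families` (list of factor-letter vectors), `levels`, `y`, `table`,
#'   `n_missing` (count of absent cells relative to the full cross).
#' @export
build_design <- function(table) {
  need <- c("participant", "frequency", "modality", "rhythmicity", "value")
  if (!all(need %in% names(table))) {
    stop("table must have columns ", paste(need, collapse = ", "))
  }
  lv <- design_levels(table)
  letters_used <- names(lv)
  cols <- factor_letter_map[letters_used]
  key <- do.call(paste, c(table[cols], sep = "\r"))
  if (anyDuplicated(key)) stop("duplicate cells in table")
  n_full <- prod(vapply(lv, length, integer(1)))

  subsets <- unlist(lapply(seq_along(letters_used), function(k) {
    utils::combn(letters_used, k, simplify = FALSE)
  }), recursive = FALSE)
  fam_names <- vapply(subsets, paste, character(1), collapse = ":")
  idx <- matrix(NA_integer_, nrow(table), length(subsets),
                dimnames = list(NULL, fam_names))
  for (s in seq_along(subsets)) {
    idx[, s] <- level_index(table, subsets[[s]], lv)
  }
  structure(
    list(idx = idx, families = stats::setNames(subsets, fam_names),
         levels = lv, y = table$value, table = table,
         n_missing = n_full - nrow(table)),
    class = "factor_design"
  )
}

# 1-based index of a row's level within the family spanned by `facs`
level_index <- function(table, facs, lv) {
  sizes <- vapply(lv[facs], length, integer(1))
  out <- rep(1L, nrow(table))
  mult <- 1L
  for (j in seq_along(facs)) {
    col <- factor_letter_map[facs[j]]
    pos <- match(table[[col]], lv[[facs[j]]])
    out <- out + (pos - 1L) * mult
    mult <- mult * sizes[j]
  }
  out
}

family_nlev <- function(design) {
  vapply(design$families, function(facs) {
    as.integer(prod(vapply(design$levels[facs], length, integer(1))))
  }, integer(1))
}

#' Fit the hierarchical factorial model
#'
#' @param design A `factor_design` from [build_design()].
#' @param chains Number of MCMC chains (>= 2).
#' @param warmup,draws Warm-up and retained iterations per chain.
#' @param thin Thinning interval (default 1).
#' @param seed RNG seed; chain seeds are derived from it.
#' @param prior_sd_beta0,prior_scale_fam,prior_scale_sigma Prior widths in
#'   units of the observations' SD (vague defaults 10, 5, 5).
#' @param keep_coef Store full coefficient draws (default: only when the
#'   design has fewer than 2000 coefficients).
#' @return An object of class `sms_bglm` with combined posterior draws of
#'   beta0, the noise scale, the family scales and the participant-averaged
#'   condition(-electrode) cell means, plus convergence diagnostics
#'   (split R-hat, bulk effective sample size).
#' @export
fit_model <- function(design, chains = 2, warmup = 500, draws = 1000,
                      thin = 1, seed = 1, prior_sd_beta0 = 10,
                      prior_scale_fam = 5, prior_scale_sigma = 5,
                      keep_coef = NULL) {
  stopifnot(inherits(design, "factor_design"))
  if (chains < 2) stop("need at least 2 chains")
  if (length(design$y) == 0) stop("empty data")
  nlev <- family_nlev(design)
  if (is.null(keep_coef)) keep_coef <- sum(nlev) < 2000
  ysd <- stats::sd(design$y)
  if (!is.finite(ysd) || ysd == 0) ysd <- 1

  # prediction grid: condition (x electrode) cells averaged over participants
  lv <- design$levels
  cond_facs <- intersect(c("F", "M", "R", "E"), names(lv))
  grid <- expand.grid(c(lv[cond_facs], lv["P"]), stringsAsFactors = FALSE)
  names(grid) <- factor_letter_map[c(cond_facs, "P")]
  cellkey <- do.call(paste, c(grid[factor_letter_map[cond_facs]], sep = "\r"))
  groups <- match(cellkey, unique(cellkey))
  pred_idx <- matrix(NA_integer_, nrow(grid), length(design$families))
  for (s in seq_along(design$families)) {
    pred_idx[, s] <- level_index(grid, design$families[[s]], lv)
  }
  cell_info <- unique(grid[factor_letter_map[cond_facs]])
  rownames(cell_info) <- NULL
  cell_info$condition <- paste(cell_info$modality, cell_info$rhythmicity,
                               cell_info$frequency, sep = "-")

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1, chains)
  runs <- lapply(seq_len(chains), function(ch) {
    set.seed(chain_seeds[ch])
    gibbs_anova(design$y, design$idx, nlev,
                prior_scale_fam = rep(prior_scale_fam * ysd, length(nlev)),
                prior_mean_beta0 = mean(design$y),
                prior_sd_beta0 = prior_sd_beta0 * ysd,
                prior_scale_sigma = prior_scale_sigma * ysd,
                n_warmup = warmup, n_save = draws, thin = thin,
                pred_idx = pred_idx, pred_group = groups,
                n_groups = max(groups), keep_coef = keep_coef)
  })

  comb <- function(field) do.call(rbind, lapply(runs, function(r) {
    m <- r[[field]]
    if (is.null(dim(m))) matrix(m, ncol = 1) else m
  }))
  cells <- comb("cells")
  scales <- comb("scales")
  colnames(scales) <- names(design$families)

  # convergence is assessed on the reported quantities (grand mean and the
  # participant-averaged cell posteriors); the noise scale is only jointly
  # identified with the deepest family's scale in the saturated model, so
  # its own diagnostics are kept separately
  mon <- cbind(beta0 = comb("beta0")[, 1], cells)
  rhats <- apply(mon, 2, split_rhat, chains = chains)
  ess <- apply(mon, 2, bulk_ess, chains = chains)
  sigma_draws <- comb("sigma")[, 1]

  max_rhat <- max(rhats, na.rm = TRUE)
  min_ess <- min(ess, na.rm = TRUE)
  # `converged` records the strict contract (R-hat < 1.05, ESS > 1000 on
  # every reported quantity); a warning is raised only for clear failures
  if (max_rhat > 1.1) {
    warning("MCMC convergence failure on reported quantities: max split ",
            "R-hat ", round(max_rhat, 3), "; increase warmup/draws")
  }
  structure(
    list(cells = cells, cell_info = cell_info,
         beta0 = comb("beta0")[, 1], sigma = sigma_draws,
         scales = scales,
         coef = if (keep_coef) comb("coef"),
         families = design$families, levels = lv,
         chains = chains, draws = draws,
         diagnostics = list(max_rhat = max_rhat, min_ess = min_ess,
                            converged = max_rhat < 1.05 && min_ess > 1000,
                            rhat = rhats, ess = ess,
                            sigma_rhat = split_rhat(sigma_draws, chains)),
         model = if ("E" %in% names(lv)) "power" else "behaviour",
         seed = seed),
    class = "sms_bglm"
  )
}

#' @export
print.sms_bglm <- function(x, ...) {
  cat(sprintf("<sms_bglm (%s): %d chains x %d draws, %d families; max R-hat %.3f, min ESS %.0f>\n",
              x$model, x$chains, x$draws, length(x$families),
              x$diagnostics$max_rhat, x$diagnostics$min_ess))
  invisible(x)
}

# split R-hat over chains-by-draws vector (draws stacked chain-major)
split_rhat <- function(x, chains) {
  n <- length(x) %/% chains
  halves <- unlist(lapply(seq_len(chains), function(ch) {
    seg <- x[((ch - 1) * n + 1):(ch * n)]
    h <- n %/% 2
    list(seg[seq_len(h)], seg[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves)
  nn <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# bulk effective sample size via Geyer initial positive sequence, pooled
bulk_ess <- function(x, chains) {
  n <- length(x) %/% chains
  acfs <- sapply(seq_len(chains), function(ch) {
    seg <- x[((ch - 1) * n + 1):(ch * n)]
    if (stats::sd(seg) == 0) return(rep(0, min(n - 1, 200)))
    stats::acf(seg, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  })
  rho <- rowMeans(acfs)
  s <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(chains * n / (1 + 2 * s), 1)
}

#' Highest-density interval of posterior draws
#'
#' Shortest contiguous interval containing at least `mass` of the draws.
#'
#' @param draws Numeric vector (>= 1000 recommended for 99% intervals).
#' @param mass Probability mass (default 0.99).
#' @return c(lower, upper).
#' @export
hdi <- function(draws, mass = 0.99) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[seq_len(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

cell_group_index <- function(fit, condition, electrode = NULL) {
  info <- fit$cell_info
  sel <- info$condition == condition
  if (!is.null(electrode)) sel <- sel & info$electrode == electrode
  g <- which(sel)
  if (length(g) != 1) {
    stop("condition/electrode does not identify one cell: ", condition,
         if (!is.null(electrode)) paste0(" @ ", electrode))
  }
  g
}

#' Posterior of one cue-condition (and electrode) cell
#'
#' Participant-averaged predicted mean for the cell, summarized by the
#' posterior mean and HDI.
#'
#' @param fit An `sms_bglm`.
#' @param condition Condition label, e.g. "AUD-ISO-1Hz".
#' @param electrode Electrode label (required for the power model).
#' @param mass HDI mass (default 0.99).
#' @return list(mean, hdi_low, hdi_high, n_draws, draws).
#' @export
cell_posterior <- function(fit, condition, electrode = NULL, mass = 0.99) {
  d <- fit$cells[, cell_group_index(fit, condition, electrode)]
  h <- hdi(d, mass)
  list(mean = mean(d), hdi_low = h[1], hdi_high = h[2],
       n_draws = length(d), draws = d)
}

#' Posterior contrast between two cue conditions
#'
#' Draw-wise difference of the two cells' posteriors (a - b). For the power
#' model the difference is significant iff its 99%-HDI excludes 0 AND the
#' absolute posterior mean exceeds the 0.4-dB floor AND the electrode is not
#' blacklisted; for the behavioural model the HDI rule alone applies.
#'
#' @param fit An `sms_bglm`.
#' @param condition_a,condition_b Condition labels.
#' @param electrode Electrode label (power model only).
#' @param mass HDI mass (default 0.99).
#' @param floor_db Effect floor in dB (default 0.4 for the power model,
#'   0 for the behavioural model).
#' @param blacklist Electrode labels never flagged significant (default:
#'   the montage's edge electrodes for the power model).
#' @return A list of class `contrast_result`.
#' @export
contrast <- function(fit, condition_a, condition_b, electrode = NULL,
                     mass = 0.99,
                     floor_db = if (fit$model == "power") 0.4 else 0,
                     blacklist = if (fit$model == "power")
                       attr(default_montage(), "blacklist") else character(0)) {
  da <- fit$cells[, cell_group_index(fit, condition_a, electrode)]
  db <- fit$cells[, cell_group_index(fit, condition_b, electrode)]
  d <- da - db
  h <- hdi(d, mass)
  blacklisted <- !is.null(electrode) && electrode %in% blacklist
  sig <- (h[1] > 0 || h[2] < 0) && abs(mean(d)) > floor_db && !blacklisted
  structure(
    list(condition_a = condition_a, condition_b = condition_b,
         electrode = electrode, diff_mean = mean(d),
         hdi_low = h[1], hdi_high = h[2], significant = sig,
         blacklisted = blacklisted, mass = mass, floor = floor_db),
    class = "contrast_result"
  )
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("%s - %s%s: %.3f [%.3f, %.3f]%s\n",
              x$condition_a, x$condition_b,
              if (!is.null(x$electrode)) paste0(" @ ", x$electrode) else "",
              x$diff_mean, x$hdi_low, x$hdi_high,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' The 12 planned condition comparisons
#'
#' Four contrasts per cue characteristic, each pair differing in exactly
#' one characteristic: frequency (1 vs 3 Hz at fixed modality/rhythmicity),
#' modality (AUD vs VIS) and rhythmicity (ISO vs POLY).
#'
#' @return data.frame(characteristic, condition_a, condition_b), 12 rows.
#' @export
comparisons_of_interest <- function() {
  rows <- list(
    c("frequency", "AUD-ISO-1Hz", "AUD-ISO-3Hz"),
    c("frequency", "AUD-POLY-1Hz", "AUD-POLY-3Hz"),
    c("frequency", "VIS-ISO-1Hz", "VIS-ISO-3Hz"),
    c("frequency", "VIS-POLY-1Hz", "VIS-POLY-3Hz"),
    c("modality", "AUD-ISO-1Hz", "VIS-ISO-1Hz"),
    c("modality", "AUD-POLY-1Hz", "VIS-POLY-1Hz"),
    c("modality", "AUD-ISO-3Hz", "VIS-ISO-3Hz"),
    c("modality", "AUD-POLY-3Hz", "VIS-POLY-3Hz"),
    c("rhythmicity", "AUD-ISO-1Hz", "AUD-POLY-1Hz"),
    c("rhythmicity", "AUD-ISO-3Hz", "AUD-POLY-3Hz"),
    c("rhythmicity", "VIS-ISO-1Hz", "VIS-POLY-1Hz"),
    c("rhythmicity", "VIS-ISO-3Hz", "VIS-POLY-3Hz")
  )
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("characteristic", "condition_a", "condition_b")
  out
}

#' Recentred (sum-to-zero) effect deflections for a participant-free family
#'
#' Derives the classical ANOVA decomposition of the participant-averaged
#' condition(-electrode) cell means at every posterior draw, returning the
#' deflections of one effect family. Only families not involving the
#' participant factor are available through this route.
#'
#' @param fit An `sms_bglm`.
#' @param family Family name, e.g. "F" or "F:E".
#' @return A draws x levels matrix of recentred deflections.
#' @export
effect_draws <- function(fit, family) {
  facs <- strsplit(family, ":", fixed = TRUE)[[1]]
  lv <- fit$levels
  cond_facs <- intersect(c("F", "M", "R", "E"), names(lv))
  if (!all(facs %in% cond_facs)) {
    stop("family must use participant-free factors present in the design")
  }
  dims <- vapply(lv[cond_facs], length, integer(1))
  nd <- nrow(fit$cells)
  arr <- array(fit$cells, c(nd, dims))

  marg <- function(subset) {
    keep <- c(1L, 1L + match(subset, cond_facs))
    apply(arr, keep, mean)
  }
  eff <- function(subset) {
    if (length(subset) == 0) return(apply(arr, 1, mean))
    m <- marg(subset)
    subs <- unlist(lapply(0:(length(subset) - 1), function(k) {
      utils::combn(subset, k, simplify = FALSE)
    }), recursive = FALSE)
    for (tt in subs) {
      e <- eff(tt)
      if (length(tt) == 0) {
        m <- m - as.vector(e)
      } else {
        perm_dims <- c(1L, 1L + match(tt, subset))
        m <- sweep_nd(m, perm_dims, e)
      }
    }
    m
  }
  out <- eff(facs)
  matrix(out, nrow = nd)
}

# subtract a lower-order effect array (dims `dims_of`) from m along those dims
sweep_nd <- function(m, dims_of, e) {
  de <- dim(m)
  perm <- c(dims_of, setdiff(seq_along(de), dims_of))
  mp <- aperm(m, perm)
  mp <- mp - as.vector(e)
  aperm(mp, order(perm))
}

#' Contrast table for all comparisons of interest
#'
#' @param fit An `sms_bglm`.
#' @param electrodes Electrode labels to evaluate (power model); NULL for
#'   the behavioural model.
#' @param ... Passed to [contrast()].
#' @return data.frame with one row per comparison (x electrode).
#' @export
contrast_table <- function(fit, electrodes = NULL, ...) {
  cmp <- comparisons_of_interest()
  if (fit$model == "behaviour") {
    rows <- lapply(seq_len(nrow(cmp)), function(i) {
      ct <- contrast(fit, cmp$condition_a[i], cmp$condition_b[i], ...)
      data.frame(characteristic = cmp$characteristic[i],
                 condition_a = ct$condition_a, condition_b = ct$condition_b,
                 diff_mean = ct$diff_mean, hdi_low = ct$hdi_low,
                 hdi_high = ct$hdi_high, significant = ct$significant)
    })
    return(do.call(rbind, rows))
  }
  if (is.null(electrodes)) electrodes <- fit$levels$E
  rows <- list()
  for (i in seq_len(nrow(cmp))) {
    for (el in electrodes) {
      ct <- contrast(fit, cmp$condition_a[i], cmp$condition_b[i],
                     electrode = el, ...)
      rows[[length(rows) + 1]] <- data.frame(
        characteristic = cmp$characteristic[i],
        condition_a = ct$condition_a, condition_b = ct$condition_b,
        electrode = el, diff_mean = ct$diff_mean, hdi_low = ct$hdi_low,
        hdi_high = ct$hdi_high, significant = ct$significant,
        blacklisted = ct$blacklisted)
    }
  }
  do.call(rbind, rows)
}
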