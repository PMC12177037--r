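# Plate-reader titration analysis: fold-sense, single-site Hill fits,
# ANOVA/Tukey detection limits, and dye-labelling stoichiometry.

#' The standard quenchbody titration concentration series
#'
#' Two-fold (approximately) serial dilution from 8000 nM down to 1 nM,
#' plus the mandatory 0 nM baseline wells.
#'
#' @return numeric vector of antigen concentrations in nM.
#' @export
qb_concentrations <- function() {
  c(0, 1, 2, 4, 8, 16, 32, 64, 125, 250, 500, 1000, 2000, 4000, 8000)
}

#' Construct or validate a titration series
#'
#' @param x data.frame with columns \code{antigen_nM}, \code{replicate},
#'   \code{fluorescence} (one row per well).
#' @param antigen optional antigen name carried as metadata.
#' @return object of class \code{titration_series} (a validated
#'   data.frame).
#' @export
titration_series <- function(x, antigen = NA_character_) {
  req <- c("antigen_nM", "replicate", "fluorescence")
  if (!all(req %in% names(x))) {
    stop("need columns: ", paste(req, collapse = ", "))
  }
  x <- as.data.frame(x)[, req]
  if (!all(is.finite(x$fluorescence)) || !all(is.finite(x$antigen_nM))) {
    stop("non-finite values in titration series")
  }
  concs <- sort(unique(x$antigen_nM))
  if (!0 %in% concs) stop("titration series must include 0 nM baseline wells")
  if (length(concs) < 2) stop("need >= 2 distinct concentrations")
  attr(x, "antigen") <- antigen
  class(x) <- c("titration_series", "data.frame")
  x
}

#' Read a titration series from CSV
#'
#' @param path CSV with columns antigen_nM, replicate, fluorescence.
#' @param ... passed to \code{titration_series}.
#' @return \code{titration_series}.
#' @export
read_titration_csv <- function(path, ...) {
  titration_series(read.table(path, header = TRUE, sep = ",",
                              stringsAsFactors = FALSE), ...)
}

#' Fold-sense normalisation
#'
#' Every well is divided by the mean fluorescence of the 0 nM baseline
#' wells; per-concentration mean and SD are computed over the replicate
#' ratios.  The maximal fold-sense -- the quenchbody's headline
#' performance number -- is the largest per-concentration mean fold.
#'
#' @param t \code{titration_series} (or coercible data.frame).
#' @return object of class \code{fold_sense}: data.frame
#'   (antigen_nM, mean_fold, sd_fold, n) plus \code{max_fold}.
#' @export
fold_sense <- function(t) {
  t <- titration_series(t, antigen = attr(t, "antigen"))
  baseline <- mean(t$fluorescence[t$antigen_nM == 0])
  if (baseline <= 0) stop("0 nM baseline mean must be > 0")
  fold <- t$fluorescence / baseline
  g <- factor(t$antigen_nM, levels = sort(unique(t$antigen_nM)))
  tab <- data.frame(
    antigen_nM = sort(unique(t$antigen_nM)),
    mean_fold = as.numeric(tapply(fold, g, mean)),
    sd_fold = as.numeric(tapply(fold, g, sd)),
    n = as.integer(tapply(fold, g, length)))
  structure(list(table = tab, max_fold = max(tab$mean_fold),
                 baseline = baseline),
            class = "fold_sense")
}

#' @export
print.fold_sense <- function(x, ...) {
  cat(sprintf("fold_sense: maximal fold %.3f over %d concentrations\n",
              x$max_fold, nrow(x$table)))
  invisible(x)
}

#' Fit the single-site Hill binding model
#'
#' The 0 nM signal is subtracted from the per-concentration means and
#' the background-subtracted response is fitted by least squares to
#' \deqn{S(c) = Bmax c^h / (EC50^h + c^h)}
#' with the Hill coefficient h free.  The fit is initialised from a
#' multi-start grid over EC50 (log-spaced across the tested
#' concentrations) and h; the best converged start by residual sum of
#' squares wins.  The fitted EC50 is the binding-affinity (KD) proxy.
#'
#' @param t \code{titration_series}, or a \code{fold_sense} object.
#' @param weights per-concentration weights (default uniform).
#' @return object of class \code{hill_fit} with \code{Bmax},
#'   \code{EC50} (nM), \code{h}, \code{residuals}, \code{rss},
#'   \code{converged}, and \code{data} (the fitted means).
#' @export
fit_binding <- function(t, weights = NULL) {
  if (inherits(t, "fold_sense")) {
    means <- t$table$mean_fold
    concs <- t$table$antigen_nM
  } else {
    t <- titration_series(t, antigen = attr(t, "antigen"))
    concs <- sort(unique(t$antigen_nM))
    means <- vapply(concs, function(cc) {
      mean(t$fluorescence[t$antigen_nM == cc])
    }, numeric(1))
  }
  s <- means - means[concs == 0]
  keep <- concs > 0
  c_nz <- concs[keep]
  y <- s[keep]
  if (length(c_nz) < 4) stop("need >= 4 non-zero concentrations")
  if (max(abs(y)) <= .Machine$double.eps^0.5 * max(abs(means))) {
    stop("flat response (Bmax ~ 0): EC50 unidentifiable")
  }
  if (is.null(weights)) weights <- rep(1, length(y))
  dat <- data.frame(c = c_nz, y = y, w = weights)
  ec50_grid <- exp(seq(log(min(c_nz)), log(max(c_nz)), length.out = 7))
  h_grid <- c(0.5, 1, 2)
  best <- NULL
  for (e0 in ec50_grid) for (h0 in h_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ Bmax * c^h / (EC50^h + c^h), data = dat,
                        start = list(Bmax = max(y), EC50 = e0, h = h0),
                        weights = dat$w,
                        lower = c(Bmax = -Inf, EC50 = 1e-9, h = 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) stop("Hill fit failed to converge from any start")
  cf <- coef(best$fit)
  structure(list(Bmax = unname(cf["Bmax"]), EC50 = unname(cf["EC50"]),
                 h = unname(cf["h"]), rss = best$rss,
                 residuals = unname(resid(best$fit)),
                 converged = best$fit$convInfo$isConv,
                 data = data.frame(antigen_nM = c_nz, response = y,
                                   fitted = fitted(best$fit))),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("hill_fit: EC50 = %.3g nM, h = %.3g, Bmax = %.4g (RSS %.3g)\n",
              x$EC50, x$h, x$Bmax, x$rss))
  invisible(x)
}

#' Lowest significantly detected antigen concentration
#'
#' One-way ANOVA over concentration groups followed by Tukey HSD
#' comparisons of each concentration against the 0 nM baseline (using
#' the full ANOVA error term).  The detection limit is the lowest
#' concentration with adjusted p below alpha; if some higher tested
#' concentration is not significant the limit is still reported but
#' flagged non-monotone.
#'
#' @param t \code{titration_series}.
#' @param alpha significance level (default 0.05).
#' @return object of class \code{detection_limit}: \code{limit_nM}
#'   (NA when nothing is significant), \code{monotone}, and the
#'   per-concentration comparison table.
#' @export
detection_limit <- function(t, alpha = 0.05) {
  t <- titration_series(t, antigen = attr(t, "antigen"))
  reps <- table(t$antigen_nM)
  if (any(reps < 2)) {
    stop("need >= 2 replicates per concentration for significance testing")
  }
  t$group <- factor(t$antigen_nM)
  fit <- aov(fluorescence ~ group, data = t)
  tk <- TukeyHSD(fit)$group
  cmp <- rownames(tk)
  # comparisons involving the 0 nM group
  parts <- strsplit(cmp, "-", fixed = TRUE)
  lhs <- vapply(parts, `[`, character(1), 1)
  rhs <- vapply(parts, `[`, character(1), 2)
  vs0 <- lhs == "0" | rhs == "0"
  conc <- as.numeric(ifelse(lhs[vs0] == "0", rhs[vs0], lhs[vs0]))
  p_adj <- tk[vs0, "p adj"]
  tab <- data.frame(antigen_nM = conc,
                    diff = tk[vs0, "diff"],
                    p_adj = p_adj,
                    # NaN p (zero residual variance, flat data) is not evidence
                    significant = !is.na(p_adj) & p_adj < alpha)
  tab <- tab[order(tab$antigen_nM), ]
  rownames(tab) <- NULL
  sig <- tab$antigen_nM[tab$significant]
  limit <- if (length(sig)) min(sig) else NA_real_
  monotone <- if (is.na(limit)) TRUE else {
    all(tab$significant[tab$antigen_nM >= limit])
  }
  if (!monotone) {
    warning("non-monotone significance pattern above the detection limit")
  }
  structure(list(limit_nM = limit, alpha = alpha, monotone = monotone,
                 comparisons = tab),
            class = "detection_limit")
}

#' @export
print.detection_limit <- function(x, ...) {
  if (is.na(x$limit_nM)) {
    cat("detection_limit: no concentration significantly different from 0 nM (alpha =",
        x$alpha, ")\n")
  } else {
    cat(sprintf("detection_limit: %g nM (alpha = %g%s)\n", x$limit_nM,
                x$alpha, if (x$monotone) "" else ", NON-MONOTONE"))
  }
  invisible(x)
}

#' Dye-labelling stoichiometry from absorbances
#'
#' Protein concentration is computed from A280 after subtracting the
#' dye's own 280 nm contribution (correction factor x A555); dye
#' concentration from A555.  Degree of labelling (DOL) is the molar
#' dye:protein ratio in percent.
#'
#' @param A280,A555 absorbances (1 cm path).
#' @param eps_protein protein molar extinction coefficient at 280 nm,
#'   1/(M cm) (default 47000, a typical tagged-nanobody value).
#' @param eps_dye dye extinction coefficient at its absorbance maximum
#'   (default 90000 for TAMRA at 555 nm).
#' @param a280_correction dye absorbance at 280 nm as a fraction of its
#'   peak absorbance (default 0.178 for TAMRA).
#' @return list with \code{protein_M}, \code{dye_M}, \code{dol_percent}.
#' @export
labelling_stoichiometry <- function(A280, A555, eps_protein = 47000,
                                    eps_dye = 90000,
                                    a280_correction = 0.178) {
  if (A280 < 0 || A555 < 0) stop("absorbances must be >= 0")
  prot_a <- A280 - a280_correction * A555
  if (prot_a < 0) {
    warning("A280 below dye correction; protein concentration clipped at 0")
    prot_a <- 0
  }
  protein <- prot_a / eps_protein
  dye <- A555 / eps_dye
  if (dye == 0) {
    dol <- 0
  } else if (protein == 0) {
    stop("protein concentration is 0: degree of labelling undefined")
  } else {
    dol <- 100 * dye / protein
  }
  list(protein_M = protein, dye_M = dye, dol_percent = dol)
}
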