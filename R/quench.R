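# Fluorophore-quencher distance statistics over trajectories.
#
# PET quenching by tryptophan is effective at fluorophore-quencher
# separations of <= 10 angstrom, so the headline statistic is the
# fraction of simulation time the dye spends within that cutoff of any
# candidate quencher ("quench-time fraction"), compared between the apo
# and antigen-bound states.

#' Define the set of candidate quencher residues
#'
#' Framework tryptophans that are buried (canonically W36 in VHH
#' domains) do not engage the dye and are excluded by default.
#'
#' @param residues character vector of selections, e.g.
#'   \code{c("A:101", "A:110", "A:115")}.
#' @param exclude residue numbers to drop before analysis (default 36,
#'   the buried framework tryptophan).
#' @return object of class \code{quencher_set}.
#' @export
quencher_set <- function(residues, exclude = 36) {
  parsed <- lapply(residues, parse_selection)
  resno <- vapply(parsed, `[[`, integer(1), "resno")
  keep <- !resno %in% exclude
  if (!any(keep)) stop("all quenchers removed by exclusions")
  structure(list(residues = residues[keep],
                 excluded = residues[!keep]),
            class = "quencher_set")
}

#' Select the conjugated fluorophore
#'
#' By default all heavy atoms of the dye residue (residue label
#' \code{"TAM"}, i.e. TAMRA) are used for the centre of mass.
#'
#' @param selector a \code{"chain:resnum"} selection, or \code{NULL} to
#'   locate the residue by label.
#' @param resid residue label used when \code{selector} is NULL.
#' @return object of class \code{fluorophore_selection}.
#' @export
fluorophore_selection <- function(selector = NULL, resid = "TAM") {
  structure(list(selector = selector, resid = resid),
            class = "fluorophore_selection")
}

.resolve_fluorophore <- function(model, fluor) {
  if (!inherits(fluor, "fluorophore_selection")) {
    fluor <- fluorophore_selection(selector = fluor)
  }
  if (!is.null(fluor$selector)) {
    idx <- select_atoms(model, fluor$selector, heavy_only = TRUE)
  } else {
    idx <- which(model$resid == fluor$resid &
                   toupper(model$element) != "H")
    if (!length(idx)) {
      stop("no residue labelled '", fluor$resid,
           "' in topology; supply an explicit selector")
    }
  }
  idx
}

# COM of one atom-index set across all frames of a replicate array:
# returns n_frames x 3.
.com_series <- function(a, idx, mass) {
  nf <- dim(a)[3]
  sub <- a[idx, , , drop = FALSE]
  m <- mass[idx] / sum(mass[idx])
  out <- matrix(NA_real_, nf, 3)
  for (ax in 1:3) {
    sl <- matrix(sub[, ax, ], nrow = length(idx))
    out[, ax] <- drop(crossprod(m, sl))
  }
  out
}

#' Fluorophore-quencher centre-of-mass distance series
#'
#' For every frame of every replicate, the Euclidean distance between
#' the dye centre of mass and each quencher residue's centre of mass,
#' plus the frame-wise minimum over quenchers ("distance to any
#' quencher").  Quencher COMs use whole-residue heavy atoms by default;
#' \code{sidechain_only = TRUE} drops the backbone atoms.
#'
#' @param traj \code{trajectory_ensemble}.
#' @param fluor \code{\link{fluorophore_selection}} (or selection string).
#' @param quenchers \code{\link{quencher_set}} (or character vector of
#'   selections, exclusion 36 applied).
#' @param sidechain_only use side-chain heavy atoms only for quencher
#'   COMs.
#' @return object of class \code{distance_series}: per replicate a
#'   matrix (frames x quenchers) plus the min series, all in angstrom.
#' @export
quencher_distances <- function(traj, fluor = fluorophore_selection(),
                               quenchers, sidechain_only = FALSE) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  if (!inherits(quenchers, "quencher_set")) quenchers <- quencher_set(quenchers)
  model <- traj$model
  fl_idx <- .resolve_fluorophore(model, fluor)
  q_idx <- lapply(quenchers$residues, function(s) {
    idx <- tryCatch(
      select_atoms(model, s, heavy_only = TRUE,
                   sidechain_only = sidechain_only),
      error = function(e) stop("quencher '", s,
                               "' not found in topology", call. = FALSE))
    idx
  })
  mass <- model$mass
  dists <- lapply(traj$replicates, function(a) {
    fcom <- .com_series(a, fl_idx, mass)
    d <- vapply(q_idx, function(idx) {
      qcom <- .com_series(a, idx, mass)
      sqrt(rowSums((fcom - qcom)^2))
    }, numeric(dim(a)[3]))
    if (is.null(dim(d))) d <- matrix(d, nrow = 1)
    colnames(d) <- quenchers$residues
    d
  })
  structure(list(distances = dists,
                 min = lapply(dists, function(d) {
                   apply(d, 1, min)
                 }),
                 quenchers = quenchers$residues,
                 state = traj$state),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat("distance_series:", x$state, "state,", length(x$distances),
      "replicate(s),", length(x$quenchers), "quencher(s):",
      paste(x$quenchers, collapse = ", "), "\n")
  invisible(x)
}

#' Quench-time fractions and distance histograms
#'
#' The quench fraction is the proportion of frames in which the dye COM
#' lies within \code{cutoff} (inclusive) of a quencher COM, computed per
#' quencher and for "any" quencher (the frame-wise minimum), per
#' replicate, and aggregated as mean and sample SD (n-1) over
#' replicates.  Histograms are count-normalised distance distributions
#' pooled over replicates, binned on [0, max distance].
#'
#' @param ds \code{distance_series}.
#' @param cutoff PET quench distance cutoff in angstrom (default 10,
#'   inclusive).
#' @param bin_width histogram bin width in angstrom (default 0.5).
#' @return object of class \code{quench_profile}.
#' @export
quench_fraction <- function(ds, cutoff = 10, bin_width = 0.5) {
  stopifnot(inherits(ds, "distance_series"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (bin_width <= 0) stop("bin width must be > 0")
  labels <- c(ds$quenchers, "any")
  per_rep <- t(vapply(seq_along(ds$distances), function(r) {
    d <- ds$distances[[r]]
    c(colMeans(d <= cutoff), mean(ds$min[[r]] <= cutoff))
  }, numeric(length(labels))))
  colnames(per_rep) <- labels
  agg <- data.frame(
    quencher = labels,
    mean = colMeans(per_rep),
    sd = if (nrow(per_rep) > 1) apply(per_rep, 2, sd) else rep(NA_real_, ncol(per_rep)),
    row.names = NULL, stringsAsFactors = FALSE)

  pooled <- lapply(seq_along(labels), function(j) {
    if (labels[j] == "any") unlist(ds$min) else {
      unlist(lapply(ds$distances, function(d) d[, j]))
    }
  })
  dmax <- max(unlist(pooled))
  breaks <- seq(0, bin_width * ceiling(dmax / bin_width + 1e-12), by = bin_width)
  if (length(breaks) < 2) breaks <- c(0, bin_width)
  prob <- vapply(pooled, function(v) {
    h <- graphics::hist(v, breaks = breaks, plot = FALSE, right = TRUE,
                        include.lowest = TRUE)
    h$counts / length(v)
  }, numeric(length(breaks) - 1))
  colnames(prob) <- labels

  structure(list(fractions = agg, per_replicate = per_rep,
                 histogram = list(breaks = breaks, prob = prob),
                 cutoff = cutoff, bin_width = bin_width,
                 state = ds$state,
                 n_frames = sum(lengths(ds$min))),
            class = "quench_profile")
}

#' @export
print.quench_profile <- function(x, ...) {
  cat("quench_profile:", x$state, "state, cutoff", x$cutoff, "A,",
      nrow(x$per_replicate), "replicate(s),", x$n_frames, "frames\n")
  f <- x$fractions
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-10s %5.1f%%%s\n", f$quencher[i], 100 * f$mean[i],
                if (!is.na(f$sd[i])) sprintf(" +/- %.1f%%", 100 * f$sd[i]) else ""))
  }
  invisible(x)
}

#' Contrast apo and antigen-bound quench profiles
#'
#' The design score for a promising quenchbody is the any-quencher
#' quench-fraction difference (apo minus bound): a large positive value
#' means the dye is parked on tryptophans when free and displaced by the
#' antigen.
#'
#' @param apo,bound \code{quench_profile} objects for the two states,
#'   computed with the same quencher set and cutoff.
#' @return object of class \code{state_contrast}: per-quencher and
#'   any-quencher delta fractions plus the two histogram sets.
#' @export
compare_states <- function(apo, bound) {
  stopifnot(inherits(apo, "quench_profile"), inherits(bound, "quench_profile"))
  if (!identical(apo$fractions$quencher, bound$fractions$quencher)) {
    stop("apo and bound profiles have different quencher sets")
  }
  if (!isTRUE(all.equal(apo$cutoff, bound$cutoff))) {
    stop("apo and bound profiles use different cutoffs")
  }
  delta <- data.frame(
    quencher = apo$fractions$quencher,
    apo = apo$fractions$mean,
    bound = bound$fractions$mean,
    delta = apo$fractions$mean - bound$fractions$mean,
    stringsAsFactors = FALSE)
  structure(list(delta = delta,
                 design_score = delta$delta[delta$quencher == "any"],
                 cutoff = apo$cutoff,
                 histograms = list(apo = apo$histogram,
                                   bound = bound$histogram)),
            class = "state_contrast")
}

#' @export
print.state_contrast <- function(x, ...) {
  cat("state_contrast: cutoff", x$cutoff, "A; any-quencher design score",
      sprintf("%.3f", x$design_score), "\n")
  print(x$delta, row.names = FALSE)
  invisible(x)
}

#' Write a quench profile to JSON and its histogram to TSV
#'
#' @param profile \code{quench_profile} or \code{state_contrast}.
#' @param json_path output JSON path (fractions and metadata).
#' @param tsv_path optional output TSV path (histogram table, one row
#'   per bin).
#' @return invisibly, the JSON path.
#' @export
write_quench_profile <- function(profile, json_path, tsv_path = NULL) {
  if (inherits(profile, "state_contrast")) {
    out <- list(delta = profile$delta, cutoff = profile$cutoff,
                design_score = profile$design_score)
    hist <- NULL
  } else {
    out <- list(state = profile$state, cutoff = profile$cutoff,
                bin_width = profile$bin_width, n_frames = profile$n_frames,
                fractions = profile$fractions,
                per_replicate = as.data.frame(profile$per_replicate))
    hist <- profile$histogram
  }
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path) && !is.null(hist)) {
    tab <- data.frame(bin_lo = hist$breaks[-length(hist$breaks)],
                      bin_hi = hist$breaks[-1], hist$prob,
                      check.names = FALSE)
    write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(json_path)
}
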