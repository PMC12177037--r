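# Seeded synthetic-data generators: surrogate tethered-fluorophore
# trajectories with analytically known contact probability, round-wise
# selection reads with junk contamination, and Hill-model plate
# titrations.  The generators provide controllable statistics for
# testing the analysis pipeline; they make no claim to physical
# fidelity (no force field, no photophysics, no sequencer error
# profile beyond uniform substitution).

#' Define a tethered-fluorophore surrogate model
#'
#' The dye end-point is drawn from an isotropic Gaussian around the
#' tether anchor (the N-terminus); quenchers sit at fixed positions.  In
#' the antigen-bound state an occlusion sphere (the antigen) rejects dye
#' positions inside it, sterically displacing the dye from the
#' quencher-proximal region.  The model's contact probability
#' P(min distance <= cutoff) is computable by numeric integration,
#' independently of any sampled trajectory.
#'
#' The defaults emulate the study conditions for a well-behaved
#' quenchbody: quenchers within reach of the tether so the apo
#' quench-time fraction is high (~0.7), and an occlusion sphere covering
#' the quencher-proximal region so the bound fraction is near zero.
#'
#' @param anchor tether anchor xyz (angstrom).
#' @param sigma isotropic Gaussian excursion scale (angstrom, > 0).
#' @param quenchers matrix (n x 3) of quencher COM positions.
#' @param occlusion list(center, radius): sphere rejecting dye positions
#'   in the bound state.  Must not cover the whole support.
#' @return object of class \code{tether_model}.
#' @export
tether_model <- function(anchor = c(0, 0, 0), sigma = 4,
                         quenchers = rbind(c(6.5, 0, 0), c(8, 3, 0), c(7, -3, 2)),
                         occlusion = list(center = c(9, 0, 0), radius = 12)) {
  if (sigma <= 0) stop("sigma must be > 0")
  quenchers <- as.matrix(quenchers)
  if (ncol(quenchers) != 3 || nrow(quenchers) < 1) {
    stop("quenchers must be an n x 3 matrix")
  }
  if (!is.null(occlusion)) {
    stopifnot(length(occlusion$center) == 3, occlusion$radius > 0)
    # rejection sampling must terminate: the anchor region must not be
    # fully swallowed (require some mass within 6 sigma outside the sphere)
    d_anchor <- sqrt(sum((anchor - occlusion$center)^2))
    if (d_anchor + 6 * sigma < occlusion$radius) {
      stop("occlusion sphere covers the entire sampling support")
    }
  }
  structure(list(anchor = as.numeric(anchor), sigma = sigma,
                 quenchers = quenchers, occlusion = occlusion),
            class = "tether_model")
}

#' Analytic contact probability of a tether model
#'
#' P(min_q ||X - q|| <= cutoff), X ~ N(anchor, sigma^2 I), conditioned
#' on X outside the occlusion sphere in the bound state.  Computed by
#' midpoint-rule quadrature on a 3D grid over anchor +/- 6 sigma
#' (independent of any Monte-Carlo sampling).
#'
#' @param model \code{tether_model}.
#' @param state \code{"apo"} (occlusion off) or \code{"bound"}.
#' @param cutoff contact cutoff, angstrom.
#' @param grid_n quadrature nodes per axis (default 161).
#' @return list with \code{any} (contact probability for the minimum
#'   over quenchers) and \code{per_quencher}.
#' @export
contact_probability <- function(model, state = c("apo", "bound"),
                                cutoff = 10, grid_n = 161) {
  state <- match.arg(state)
  stopifnot(inherits(model, "tether_model"))
  g <- seq(-6 * model$sigma, 6 * model$sigma, length.out = grid_n)
  w1 <- stats::dnorm(g, sd = model$sigma) * (g[2] - g[1])
  gx <- model$anchor[1] + g; gy <- model$anchor[2] + g; gz <- model$anchor[3] + g
  xy <- cbind(rep(gx, times = grid_n), rep(gy, each = grid_n))
  wxy <- rep(w1, times = grid_n) * rep(w1, each = grid_n)
  nq <- nrow(model$quenchers)
  num_any <- 0; num_per <- numeric(nq); denom <- 0
  occl <- if (state == "bound") model$occlusion else NULL
  for (k in seq_len(grid_n)) {
    z <- gz[k]
    w <- wxy * w1[k]
    if (!is.null(occl)) {
      inside <- (xy[, 1] - occl$center[1])^2 + (xy[, 2] - occl$center[2])^2 +
        (z - occl$center[3])^2 <= occl$radius^2
      w[inside] <- 0
    }
    d2 <- vapply(seq_len(nq), function(q) {
      (xy[, 1] - model$quenchers[q, 1])^2 +
        (xy[, 2] - model$quenchers[q, 2])^2 +
        (z - model$quenchers[q, 3])^2
    }, numeric(nrow(xy)))
    hit <- d2 <= cutoff^2
    denom <- denom + sum(w)
    num_per <- num_per + colSums(w * hit)
    num_any <- num_any + sum(w[rowSums(hit) > 0])
  }
  if (denom <= 0) stop("occlusion leaves no probability mass")
  list(any = num_any / denom,
       per_quencher = num_per / denom)
}

# mass-balanced 3-atom pseudo-residue offsets (C, N, O): COM at origin
.pseudo_atoms <- function() {
  m <- c(C = 12.011, N = 14.007, O = 15.999)
  s <- 0.8
  d1 <- c(s, 0, 0); d2 <- c(0, s, 0)
  d3 <- -(m[1] * d1 + m[2] * d2) / m[3]
  list(mass = m, offsets = rbind(d1, d2, d3),
       element = c("C", "N", "O"), atom = c("C1", "N1", "O1"))
}

#' Simulate a surrogate fluorophore trajectory
#'
#' Samples dye end-points from the tether model (rejection sampling
#' against the occlusion sphere in the bound state) and builds a
#' \code{trajectory_ensemble} whose topology uses a mass-balanced
#' 3-atom pseudo-residue for the dye (label TAM) and for each quencher
#' (label TRP), so downstream centre-of-mass code paths are exercised
#' with non-trivial masses.  The analytic contact probability is
#' returned alongside.
#'
#' @param model \code{tether_model}.
#' @param state \code{"apo"} or \code{"bound"}.
#' @param frames frames per replicate.
#' @param replicates number of independent replicates.
#' @param cutoff contact cutoff for the analytic expectation.
#' @param seed integer seed.
#' @param path optional path: write the trajectory as multi-model PDB,
#'   with a JSON ground-truth sidecar (\code{<path>.truth.json}).
#' @return list with \code{traj} (\code{trajectory_ensemble}),
#'   \code{expected} (analytic contact probabilities) and
#'   \code{quencher_selections} (selection strings for the quenchers).
#' @export
simulate_trajectory <- function(model, state = c("apo", "bound"),
                                frames = 1000, replicates = 1, cutoff = 10,
                                seed = NULL, path = NULL) {
  state <- match.arg(state)
  stopifnot(inherits(model, "tether_model"), frames >= 1, replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  pa <- .pseudo_atoms()
  nq <- nrow(model$quenchers)
  # topology: dye residue 1 (chain F), quencher residues 101, 102, ... (chain A)
  resno <- c(rep(1L, 3), rep(100L + seq_len(nq), each = 3))
  atoms <- data.frame(
    atom = rep(pa$atom, nq + 1),
    element = rep(pa$element, nq + 1),
    resid = c(rep("TAM", 3), rep("TRP", 3 * nq)),
    resno = resno,
    chain = c(rep("F", 3), rep("A", 3 * nq)),
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  q_atoms <- do.call(rbind, lapply(seq_len(nq), function(q) {
    sweep(pa$offsets, 2, model$quenchers[q, ], "+")
  }))
  occl <- if (state == "bound") model$occlusion else NULL
  sample_points <- function(n) {
    pts <- matrix(NA_real_, n, 3)
    filled <- 0
    while (filled < n) {
      m <- max(2 * (n - filled), 64)
      cand <- matrix(rnorm(3 * m, sd = model$sigma), ncol = 3)
      cand <- sweep(cand, 2, model$anchor, "+")
      if (!is.null(occl)) {
        keep <- rowSums(sweep(cand, 2, occl$center)^2) > occl$radius^2
        cand <- cand[keep, , drop = FALSE]
      }
      take <- min(nrow(cand), n - filled)
      if (take > 0) pts[filled + seq_len(take), ] <- cand[seq_len(take), ]
      filled <- filled + take
    }
    pts
  }
  reps <- lapply(seq_len(replicates), function(r) {
    pts <- sample_points(frames)
    a <- array(NA_real_, c(nrow(atoms), 3, frames))
    for (f in seq_len(frames)) {
      a[1:3, , f] <- sweep(pa$offsets, 2, pts[f, ], "+")
      a[4:nrow(atoms), , f] <- q_atoms
    }
    a
  })
  # first frame into the topology coordinates
  atoms[, c("x", "y", "z")] <- reps[[1]][, , 1]
  traj <- trajectory_ensemble(structure_model(atoms), reps, state)
  expected <- contact_probability(model, state, cutoff)
  out <- list(traj = traj,
              expected = expected,
              quencher_selections = paste0("A:", 100 + seq_len(nq)))
  if (!is.null(path)) {
    write_pdb_trajectory(traj, path)
    jsonlite::write_json(list(state = state, cutoff = cutoff,
                              expected_any = expected$any,
                              expected_per_quencher = expected$per_quencher,
                              sigma = model$sigma, frames = frames,
                              replicates = replicates),
                         paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Specify a selection simulation
#'
#' @param variants list of \code{variant_gene} (the library).
#' @param fitness per-variant selection weights (>= 0, not all zero).
#' @param rounds number of selection rounds.
#' @param reads_per_round sequencing depth per round.
#' @param junk_rate fraction of reads replaced by misassembled
#'   (frameshifted) molecules, in [0, 1).
#' @param error_rate per-base substitution error rate, in [0, 1).
#' @return object of class \code{selection_sim_spec}.
#' @export
selection_sim_spec <- function(variants, fitness = NULL, rounds = 5,
                               reads_per_round = 1e4, junk_rate = 0.3,
                               error_rate = 0) {
  if (!length(variants)) stop("need >= 1 variant")
  if (is.null(fitness)) fitness <- rep(1, length(variants))
  if (length(fitness) != length(variants) || any(fitness < 0) ||
      all(fitness == 0)) {
    stop("fitness must be >= 0, length-matched, not all zero")
  }
  if (junk_rate < 0 || junk_rate >= 1 || error_rate < 0 || error_rate >= 1) {
    stop("rates must lie in [0, 1)")
  }
  structure(list(variants = variants, fitness = fitness, rounds = rounds,
                 reads_per_round = reads_per_round, junk_rate = junk_rate,
                 error_rate = error_rate),
            class = "selection_sim_spec")
}

# frameshift a cassette by deleting one nucleotide inside the CDR
# region of the ORF -- guarantees failure of the frame criterion
.frameshift_read <- function(cassette, orf_offset, cdrs) {
  idx <- cdr_indices(cdrs)
  aa_pos <- idx[sample.int(length(idx), 1)]
  nt <- orf_offset + 3 * (aa_pos - 1) + sample.int(3, 1)  # 1-based nt in cassette
  paste0(substr(cassette, 1, nt - 1), substr(cassette, nt + 1, nchar(cassette)))
}

.mutate_bases <- function(reads, rate) {
  if (rate <= 0) return(reads)
  vapply(reads, function(r) {
    n <- nchar(r)
    k <- rbinom(1, n, rate)
    if (k == 0) return(r)
    pos <- sample.int(n, k)
    ch <- strsplit(r, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate multi-round selection reads
#'
#' Round r variant counts are multinomial with probabilities
#' proportional to (realised round r-1 frequency) x fitness, starting
#' from a uniform library.  Junk reads -- cassettes with a 1-nt deletion
#' inside a CDR, so they fail the frame criterion of the quality filter
#' -- are injected at the stated rate.  Reads are full expression
#' cassettes; ground truth (true frequencies and junk labels) is always
#' returned and written alongside any FASTQ output.
#'
#' @param spec \code{selection_sim_spec}.
#' @param seed integer seed.
#' @param dir optional directory: write per-round FASTQ files
#'   (\code{round<r>.fastq}) and \code{truth.json}.
#' @param elements \code{\link{cassette_elements}}.
#' @return list with \code{reads} (list of per-round character vectors,
#'   shuffled), \code{truth} (list: per-round true frequencies matrix,
#'   junk counts) and \code{files} (if written).
#' @export
simulate_selection <- function(spec, seed = NULL, dir = NULL,
                               elements = cassette_elements()) {
  stopifnot(inherits(spec, "selection_sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  nv <- length(spec$variants)
  cassettes <- vapply(spec$variants, assemble_cassette, character(1),
                      elements = elements)
  orf_offset <- nchar(elements$fwd_primer) + nchar(elements$t7_promoter) +
    nchar(elements$rbs) + 3  # nt before the first variant codon
  ids <- vapply(spec$variants, `[[`, character(1), "id")
  freq <- rep(1 / nv, nv)
  true_freq <- matrix(NA_real_, nv, spec$rounds,
                      dimnames = list(ids, paste0("round", seq_len(spec$rounds))))
  junk_n <- integer(spec$rounds)
  reads <- vector("list", spec$rounds)
  for (r in seq_len(spec$rounds)) {
    p <- freq * spec$fitness
    p <- p / sum(p)
    true_freq[, r] <- p
    n_junk <- rbinom(1, spec$reads_per_round, spec$junk_rate)
    n_good <- spec$reads_per_round - n_junk
    counts <- drop(rmultinom(1, n_good, p))
    good <- rep(cassettes, counts)
    junk <- character(n_junk)
    if (n_junk > 0) {
      src <- sample.int(nv, n_junk, replace = TRUE, prob = p)
      junk <- vapply(src, function(i) {
        .frameshift_read(cassettes[i], orf_offset, spec$variants[[i]]$cdrs)
      }, character(1))
    }
    rr <- .mutate_bases(c(good, junk), spec$error_rate)
    reads[[r]] <- rr[sample.int(length(rr))]
    junk_n[r] <- n_junk
    freq <- if (n_good > 0) counts / n_good else freq
  }
  names(reads) <- paste0("round", seq_len(spec$rounds))
  truth <- list(true_freq = true_freq, junk_reads = junk_n,
                junk_rate = spec$junk_rate, fitness = setNames(spec$fitness, ids))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- vapply(seq_len(spec$rounds), function(r) {
      f <- file.path(dir, paste0("round", r, ".fastq"))
      rd <- reads[[r]]
      writeLines(as.vector(rbind(paste0("@read", seq_along(rd)), rd, "+",
                                 vapply(nchar(rd), function(n) {
                                   strrep("I", n)
                                 }, character(1)))), f)
      f
    }, character(1))
    jsonlite::write_json(list(true_freq = as.data.frame(true_freq),
                              junk_reads = junk_n,
                              junk_rate = spec$junk_rate),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(dir, "truth.json"))
  }
  list(reads = reads, truth = truth, files = files)
}

#' Simulate a plate titration
#'
#' Raw fluorescence is I0 + Bmax c^h / (EC50^h + c^h) plus Gaussian
#' noise (SD expressed as a fraction of Bmax); replicate wells are
#' independent.  Defaults emulate a well-behaved quenchbody titration:
#' EC50 14 nM, Hill slope 1, plateau at 1.5x baseline, triplicate wells
#' over the standard concentration series.
#'
#' @param Bmax response amplitude, a.u.
#' @param EC50 half-maximal concentration, nM.
#' @param h Hill coefficient.
#' @param I0 baseline (0 nM) intensity, a.u.
#' @param noise_sd Gaussian noise SD as a fraction of Bmax.
#' @param replicates wells per concentration.
#' @param concentrations concentration grid in nM (must include 0).
#' @param seed integer seed.
#' @return \code{titration_series} with attribute \code{truth} (the
#'   generating parameters).
#' @export
simulate_plate <- function(Bmax = 500, EC50 = 14, h = 1, I0 = 1000,
                           noise_sd = 0.05, replicates = 3,
                           concentrations = qb_concentrations(),
                           seed = NULL) {
  stopifnot(Bmax >= 0, EC50 > 0, h > 0, I0 > 0, noise_sd >= 0,
            replicates >= 1)
  if (!0 %in% concentrations) stop("concentration grid must include 0 nM")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates),
                      antigen_nM = sort(concentrations))
  mu <- I0 + Bmax * grid$antigen_nM^h / (EC50^h + grid$antigen_nM^h)
  y <- mu + rnorm(nrow(grid), sd = noise_sd * Bmax)
  ts <- titration_series(data.frame(antigen_nM = grid$antigen_nM,
                                    replicate = grid$replicate,
                                    fluorescence = y))
  attr(ts, "truth") <- list(Bmax = Bmax, EC50 = EC50, h = h, I0 = I0,
                            noise_sd = noise_sd)
  ts
}
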