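# Shared in-code fixtures: tiny structure models and trajectories built
# by hand, plus brute-force oracles kept deliberately independent of the
# package's vectorised code paths.

# A toy topology: one 3-atom dye pseudo-residue (TAM, chain F) plus one
# 3-atom Trp pseudo-residue per quencher position (chain A, resno 101+).
toy_topology <- function(n_quenchers = 1) {
  mk <- function(resid, resno, chain) {
    data.frame(atom = c("C1", "N1", "O1"), element = c("C", "N", "O"),
               resid = resid, resno = resno, chain = chain,
               x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, c(list(mk("TAM", 1L, "F")),
                           lapply(seq_len(n_quenchers), function(q) {
                             mk("TRP", 100L + q, "A")
                           })))
  structure_model(rows)
}

# Place each residue's 3 atoms so that the residue COM sits exactly at
# `centers` (one row per residue) -- offsets are mass-balanced.
place_residues <- function(model, centers) {
  m <- c(12.011, 14.007, 15.999)
  s <- 0.6
  d <- rbind(c(s, 0, 0), c(0, s, 0), -(m[1] * c(s, 0, 0) + m[2] * c(0, s, 0)) / m[3])
  coords <- matrix(NA_real_, nrow(model), 3)
  for (r in seq_len(nrow(centers))) {
    coords[(3 * r - 2):(3 * r), ] <- sweep(d, 2, centers[r, ], "+")
  }
  coords
}

# Trajectory from a list of per-frame residue-center matrices.
toy_trajectory <- function(frame_centers, state = "apo", n_quenchers = NULL) {
  if (is.null(n_quenchers)) n_quenchers <- nrow(frame_centers[[1]]) - 1
  model <- toy_topology(n_quenchers)
  a <- array(NA_real_, c(nrow(model), 3, length(frame_centers)))
  for (f in seq_along(frame_centers)) {
    a[, , f] <- place_residues(model, frame_centers[[f]])
  }
  model[, c("x", "y", "z")] <- a[, , 1]
  trajectory_ensemble(structure_model(model), list(a), state)
}

# Brute-force oracle: per-frame COM-COM distances computed by direct
# summation, one atom at a time.
brute_distances <- function(traj, fluor_resno = 1, q_resnos) {
  model <- traj$model
  com_of <- function(coords, idx) {
    tot <- c(0, 0, 0); msum <- 0
    for (i in idx) {
      tot <- tot + model$mass[i] * coords[i, ]
      msum <- msum + model$mass[i]
    }
    tot / msum
  }
  lapply(traj$replicates, function(a) {
    nf <- dim(a)[3]
    out <- matrix(NA_real_, nf, length(q_resnos))
    f_idx <- which(model$resno == fluor_resno & model$element != "H")
    for (f in seq_len(nf)) {
      fc <- com_of(a[, , f], f_idx)
      for (k in seq_along(q_resnos)) {
        qi <- which(model$resno == q_resnos[k] & model$element != "H")
        qc <- com_of(a[, , f], qi)
        out[f, k] <- sqrt(sum((fc - qc)^2))
      }
    }
    out
  })
}

# Random rigid motion (proper rotation + translation).
random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 20))
}

apply_rigid <- function(traj, rigid) {
  reps <- lapply(traj$replicates, function(a) {
    out <- a
    for (f in seq_len(dim(a)[3])) {
      out[, , f] <- sweep(a[, , f] %*% t(rigid$R), 2, rigid$t, "+")
    }
    out
  })
  model <- traj$model
  model[, c("x", "y", "z")] <- reps[[1]][, , 1]
  trajectory_ensemble(structure_model(as.data.frame(model)), reps, traj$state,
                      traj$frame_interval)
}

# A 128-aa nanobody stand-in with chosen residues at chosen display
# positions (default body is the optimised scaffold framework pattern).
standin_record <- function(overrides = c(), id = "standin") {
  aa <- rep("G", 128)
  aa[c(22, 96)] <- "C"
  for (p in names(overrides)) aa[as.integer(p)] <- overrides[[p]]
  nanobody_record(id, paste(aa, collapse = ""))
}

standin_cdrs <- function() cdr_map(c(26, 36), c(50, 67), c(97, 118), 128)
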