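# Independent oracles used to cross-check the package's own algorithms.
# Each is deliberately written with a different algorithm (and different
# quadrature / data structures) than the implementation it checks.

# Brute-force SASA by latitude-longitude quadrature on each atom's
# solvent-expanded sphere: band-weighted grid points, point exposed iff
# outside every neighbour's expanded sphere. Returns per-atom areas.
oracle_sasa <- function(xyz, radius, probe = 1.4, n_theta = 40,
                        n_phi = 80) {
  n <- nrow(xyz)
  areas <- numeric(n)
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  # quadrature weight of each (theta, phi) cell on a unit sphere
  w_theta <- sin(theta) * (pi / n_theta) * (2 * pi / n_phi)
  grid <- expand.grid(t = seq_len(n_theta), p = seq_len(n_phi))
  ux <- sin(theta[grid$t]) * cos(phi[grid$p])
  uy <- sin(theta[grid$t]) * sin(phi[grid$p])
  uz <- cos(theta[grid$t])
  w <- w_theta[grid$t]
  for (i in seq_len(n)) {
    ri <- radius[i] + probe
    px <- xyz[i, 1] + ri * ux
    py <- xyz[i, 2] + ri * uy
    pz <- xyz[i, 3] + ri * uz
    exposed <- rep(TRUE, length(px))
    for (j in seq_len(n)) {
      if (j == i) next
      rj <- radius[j] + probe
      d2 <- (px - xyz[j, 1])^2 + (py - xyz[j, 2])^2 + (pz - xyz[j, 3])^2
      exposed <- exposed & d2 >= rj^2
    }
    areas[i] <- ri^2 * sum(w[exposed])
  }
  areas
}

# Brute-force cross-chain contact detection: plain double loop over atom
# pairs, no compiled code.
oracle_contact_residues <- function(model, chain_a, chain_b, cutoff = 5.0) {
  at <- atoms(model)
  a <- at[at$chain == chain_a, , drop = FALSE]
  b <- at[at$chain == chain_b, , drop = FALSE]
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    d2 <- (a$x[i] - b$x)^2 + (a$y[i] - b$y)^2 + (a$z[i] - b$z)^2
    hit[i] <- any(d2 <= cutoff^2)
  }
  sort(unique(a$resno[hit]))
}

# Exhaustive region derivation: flagged positions split wherever the gap
# to the previous flagged position exceeds maxGap + 1, then span-filtered.
oracle_regions <- function(flags, min_length, max_gap) {
  resno <- if (is.null(names(flags))) seq_along(flags)
           else as.integer(names(flags))
  pos <- resno[as.logical(flags)]
  if (!length(pos)) return(data.frame(start = integer(), end = integer()))
  grp <- cumsum(c(1L, diff(pos) > max_gap + 1L))
  out <- do.call(rbind, lapply(split(pos, grp), function(p)
    data.frame(start = min(p), end = max(p))))
  out <- out[out$end - out$start + 1L >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive consensus vote count.
oracle_votes <- function(predictions, min_votes) {
  resno <- sort(predictions[[1]]$resno)
  active <- integer()
  for (r in resno) {
    v <- 0L
    for (p in predictions)
      if (p$flag[match(r, p$resno)]) v <- v + 1L
    if (v >= min_votes) active <- c(active, r)
  }
  active
}

# Brute-force passive derivation: residues with any atom within radius of
# any active-residue atom, surface-filtered by relative SASA.
oracle_passive <- function(model, active, chain, radius, rsa_min) {
  at <- atoms(model)
  a <- at[at$chain == chain, , drop = FALSE]
  act <- a[a$resno %in% active, , drop = FALSE]
  near <- integer()
  for (r in unique(a$resno)) {
    ra <- a[a$resno == r, , drop = FALSE]
    found <- FALSE
    for (i in seq_len(nrow(ra)))
      for (j in seq_len(nrow(act))) {
        d <- sqrt((ra$x[i] - act$x[j])^2 + (ra$y[i] - act$y[j])^2 +
                  (ra$z[i] - act$z[j])^2)
        if (d <= radius) { found <- TRUE; break }
      }
    if (found) near <- c(near, r)
  }
  rsa <- relativeSasa(model, chains = chain)
  surface <- rsa$resno[rsa$rsa >= rsa_min]
  sort(setdiff(intersect(near, surface), active))
}

# Small overlapping synthetic peptide (atoms close enough to occlude each
# other) used for SASA cross-checks.
make_test_peptide <- function() {
  rows <- list()
  for (r in 1:5) {
    cx <- (r - 1) * 3.0
    rows[[r]] <- data.frame(
      chain = "A", resno = r, resid = c("ALA", "GLY", "SER", "VAL", "THR")[r],
      elety = c("N", "CA", "C"), element = c("N", "C", "C"),
      x = cx + c(-1.2, 0, 1.2), y = c(0.5, 0, 0.5), z = c(0, 0.8, 0),
      stringsAsFactors = FALSE)
  }
  StructureModel(do.call(rbind, rows), source = "SYNTHETIC")
}
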