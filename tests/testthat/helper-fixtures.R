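# Fixtures built in code: random atom clouds, toy structures, stub backends.

# A random cloud of heavy atoms, each in its own residue, inside a cube of
# the given edge (Angstrom) - so pair eligibility is purely distance-driven.
makeAtomCloud <- function(n, seed = 1, edge = 8, elements = c("C", "N", "O")) {
  set.seed(seed)
  a <- data.frame(
    name = paste0("X", seq_len(n)),
    element = sample(elements, n, replace = TRUE),
    x = runif(n, 0, edge), y = runif(n, 0, edge), z = runif(n, 0, edge),
    chain = "A", res_seq = seq_len(n), icode = "",
    res_name = "ALA", is_backbone = FALSE, het = FALSE,
    stringsAsFactors = FALSE)
  ThermoShift:::newStructure(paste0("cloud", n, "s", seed), a)
}

# A two-atom structure at a prescribed separation.
makePair <- function(d, elements = c("C", "C"), backbone = c(FALSE, FALSE),
                     res_seq = c(1L, 2L), names = c("X1", "X2")) {
  a <- data.frame(
    name = names, element = elements,
    x = c(0, d), y = c(0, 0), z = c(0, 0),
    chain = "A", res_seq = res_seq, icode = "",
    res_name = "ALA", is_backbone = backbone, het = FALSE,
    stringsAsFactors = FALSE)
  ThermoShift:::newStructure("pair", a)
}

# Brute-force all-pairs distance-bin histogram (the independent oracle).
bruteFreq <- function(structure) {
  a <- atoms(structure)
  a <- a[a$element != "H", , drop = FALSE]
  xyz <- cbind(a$x, a$y, a$z)
  n <- nrow(a)
  edges <- c(0, seq(2.1, 3.3, by = 0.1))
  counts <- numeric(13)
  denom <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    cut <- if (a$element[i] == "S" || a$element[j] == "S") 2.2 else 1.9
    if (d < cut) next          # covalent
    if (d >= 6) next           # outside denominator
    denom <- denom + 1
    for (b in 1:13) if (d >= edges[b] && d < edges[b + 1]) counts[b] <- counts[b] + 1
  }
  if (denom == 0) rep(0, 13) else counts / denom
}

# Brute-force H-bond scan.
bruteHBonds <- function(structure) {
  a <- atoms(structure)
  a <- a[a$element %in% c("N", "O"), , drop = FALSE]
  n <- nrow(a)
  bb <- 0; sc <- 0
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- a$res_seq[i] == a$res_seq[j] && a$chain[i] == a$chain[j] &&
      a$icode[i] == a$icode[j]
    if (same) next
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    if (d >= 2.5 && d <= 3.5) {
      if (a$is_backbone[i] && a$is_backbone[j]) bb <- bb + 1 else sc <- sc + 1
    }
  }
  c(backbone = bb, sidechain = sc)
}

# Apply a rigid motion (rotation + translation) to a structure.
rigidMove <- function(structure, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  R <- Rx %*% Ry %*% Rz
  tr <- runif(3, -20, 20)
  a <- atoms(structure)
  xyz <- t(R %*% t(cbind(a$x, a$y, a$z))) + rep(tr, each = nrow(a))
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  ThermoShift:::newStructure(structureId(structure), a)
}

# A feature backend stub returning a constant vector (for caching/guard tests).
constantBackend <- function(value = 1) {
  function(structure) stats::setNames(rep(value, 29), featureSchema())
}

# First standard residue of a structure and a legal single-site spec on it.
firstSiteSpec <- function(structure, to = NULL) {
  r <- residues(structure)
  wt <- ThermoShift:::AA1_FROM_3[[r$res_name[1]]]
  if (is.null(to)) to <- setdiff(c("L", "V", "A"), wt)[1]
  parseMutationSpec(sprintf("%s:%s%d%s", r$chain[1], wt, r$res_seq[1], to))
}
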