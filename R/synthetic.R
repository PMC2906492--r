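# Synthetic inputs: toy helical structures and encoded training tables with
# controlled signal, emulating the class structure of curated
# thermostability mutant collections (3366 mutants, 836 stabilizing with
# ddG 1.50 +/- 1.36 kcal/mol, 2530 destabilizing with -1.77 +/- 1.03,
# site counts 1..9, |ddG| growing with site count).

#' Configuration for the synthetic dataset generator
#'
#' Defaults restate the composition of the real training collection the
#' generator emulates: 836/3366 stabilizing mutants, per-class ddG
#' mean +/- sd of 1.50 +/- 1.36 (stabilizing) and -1.77 +/- 1.03 kcal/mol
#' (destabilizing), ddG clipped to the observed [-12.23, 13.7] envelope, and
#' site-count proportions 2765:441:93:67 for 1/2/3/>=4 sites.
#'
#' @param n_mutants number of mutants to generate.
#' @param positive_fraction stabilizing fraction; allocated exactly
#'   (`round(n * fraction)` positives).
#' @param pos_mean,pos_sd,neg_mean,neg_sd per-class ddG parameters
#'   (kcal/mol) of the truncated normals.
#' @param signal_features indices in 1..29 of the V-block features carrying
#'   the latent signal (their Y-block partners, indices +29, inherit it
#'   through the percentile coupling).
#' @param noise_scale noise sd as a multiple of the latent signal sd
#'   (1 = signal-to-noise 1).
#' @param multi_site_probs probabilities of 1..9 mutation sites.
#' @param n_proteins number of synthetic protein identifiers.
#' @param seed integer RNG seed.
#' @return validated config list.
#' @export
syntheticConfig <- function(n_mutants = 3366L,
                            positive_fraction = 836 / 3366,
                            pos_mean = 1.50, pos_sd = 1.36,
                            neg_mean = -1.77, neg_sd = 1.03,
                            signal_features = 1:6,
                            noise_scale = 1.0,
                            multi_site_probs = c(2765, 441, 93, 47, 10,
                                                 4, 3, 2, 1) / 3366,
                            n_proteins = NULL,
                            seed = 1L) {
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop("positive_fraction must be in (0, 1)")
  if (pos_mean <= 0 || neg_mean >= 0)
    stop("pos_mean must be > 0 and neg_mean < 0")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  if (length(multi_site_probs) != 9L || any(multi_site_probs < 0) ||
      abs(sum(multi_site_probs) - 1) > 1e-8)
    stop("multi_site_probs must be 9 probabilities summing to 1")
  if (any(signal_features < 1 | signal_features > N_FEATURES))
    stop("signal_features must index 1..29 (V block)")
  if (is.null(n_proteins)) n_proteins <- max(1L, round(n_mutants / 30))
  list(n_mutants = as.integer(n_mutants),
       positive_fraction = positive_fraction,
       pos_mean = pos_mean, pos_sd = pos_sd,
       neg_mean = neg_mean, neg_sd = neg_sd,
       signal_features = as.integer(signal_features),
       noise_scale = noise_scale,
       multi_site_probs = multi_site_probs,
       n_proteins = as.integer(n_proteins),
       ddg_clip = c(-12.23, 13.7),
       seed = as.integer(seed))
}

#' Generate an ideal alpha-helical toy structure
#'
#' Builds a single-chain poly-residue alpha helix (rise 1.5 Angstrom and
#' twist 100 degrees per residue) with N, CA, C, O and CB atoms (no CB for
#' glycine), residues numbered 1..length, residue types drawn from the 20
#' standard amino acids under a seeded stream. Useful as a self-contained
#' stand-in for a PDB structure: consecutive CA-CA distances are ~3.8 A and
#' the i -> i+4 backbone O..N contacts form real geometric hydrogen bonds.
#'
#' @param length number of residues (>= 1).
#' @param seed integer RNG seed.
#' @param chain chain identifier.
#' @return A [ProteinStructure-class].
#' @examples
#' s <- generateToyStructure(5, seed = 1)
#' residues(s)
#' @export
generateToyStructure <- function(length, seed = 1L, chain = "A") {
  length <- as.integer(length)
  if (length < 1L) stop("length must be >= 1")
  resn <- withSeed(seed, sample(AA3, length, replace = TRUE))

  # helix parameters: CA radius 2.3 A, 100 deg/residue, 1.5 A rise.
  twist <- 100 * pi / 180
  rise <- 1.5
  helixPoint <- function(i, radius, phase, dz)
    c(radius * cos(i * twist + phase), radius * sin(i * twist + phase),
      i * rise + dz)

  rows <- list()
  for (i in seq_len(length)) {
    # local offsets approximating ideal backbone geometry on the helix
    atomsOf <- rbind(
      N  = helixPoint(i, 1.60, -0.50, -0.95),
      CA = helixPoint(i, 2.30,  0.00,  0.00),
      C  = helixPoint(i, 1.70,  0.45,  1.05),
      O  = helixPoint(i, 2.10,  0.55,  2.25))
    if (resn[i] != "GLY") {
      ca <- atomsOf["CA", ]
      cb <- idealCBeta(atomsOf["N", ], ca, atomsOf["C", ])
      atomsOf <- rbind(atomsOf, CB = cb)
    }
    nm <- rownames(atomsOf)
    rows[[i]] <- data.frame(
      name = nm, element = substr(nm, 1, 1),
      x = atomsOf[, 1], y = atomsOf[, 2], z = atomsOf[, 3],
      chain = chain, res_seq = i, icode = "",
      res_name = resn[i], is_backbone = nm %in% BACKBONE_ATOMS,
      het = FALSE, stringsAsFactors = FALSE)
  }
  a <- do.call(rbind, rows)
  a$x <- round(a$x, 3); a$y <- round(a$y, 3); a$z <- round(a$z, 3)
  newStructure(sprintf("toy%d_s%d", length, seed), a)
}

# Exact integer allocation of site counts 1..9 from probabilities.
.allocateCounts <- function(n, probs) {
  cnt <- floor(n * probs)
  rem <- n - sum(cnt)
  if (rem > 0) {
    frac <- n * probs - cnt
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  as.integer(cnt)
}

#' Generate a synthetic encoded dataset
#'
#' Draws per-class ddG from truncated normals (stabilizing > 0,
#' destabilizing < 0; exact class allocation, so the default configuration
#' yields exactly 836 positives out of 3366). The truncated-normal location
#' is moment-matched so the post-truncation class means equal the configured
#' `pos_mean`/`neg_mean`; the realized spreads differ slightly from the
#' nominal sds because of the truncation. ddG is clipped to the configured
#' envelope, site counts are assigned so that mean |ddG| increases with the
#' number of sites, and builds 58-column encoded features: the latent signal
#' `tanh(ddG / 4)` enters the configured V-block columns as a linear map
#' plus Gaussian noise (sd = `noise_scale` times the signal sd), each
#' Y-block column is the midrank percentile of its V partner (preserving the
#' V/Y coupling of real encodings), and the remaining columns are pure
#' noise. Bit-reproducible from config + seed.
#'
#' @param config a [syntheticConfig()] list.
#' @return list: `data` (encoded data.frame: `protein_id`, `mutation_spec`,
#'   `ddg`, `n_sites`, `z1..z58`), `manifest` (config echo).
#' @export
generateDataset <- function(config = syntheticConfig()) {
  cf <- config
  n <- cf$n_mutants
  npos <- as.integer(round(n * cf$positive_fraction))
  nneg <- n - npos
  if (npos < 1L || nneg < 1L) stop("both classes need at least one mutant")

  # moment-match the truncated normals: choose the location parameter so the
  # post-truncation class mean equals the configured mean
  locFor <- function(target, sd, a, b) {
    stats::uniroot(function(m)
      truncnorm::etruncnorm(a = a, b = b, mean = m, sd = sd) - target,
      interval = c(target - 6 * sd, target + 6 * sd), tol = 1e-9)$root
  }
  muPos <- locFor(cf$pos_mean, cf$pos_sd, 0, cf$ddg_clip[2])
  muNeg <- locFor(cf$neg_mean, cf$neg_sd, cf$ddg_clip[1], 0)

  withSeed(cf$seed, {
    ddg <- c(truncnorm::rtruncnorm(npos, a = 1e-6, b = cf$ddg_clip[2],
                                   mean = muPos, sd = cf$pos_sd),
             truncnorm::rtruncnorm(nneg, a = cf$ddg_clip[1], b = -1e-6,
                                   mean = muNeg, sd = cf$neg_sd))
    ddg <- pmin(pmax(ddg, cf$ddg_clip[1]), cf$ddg_clip[2])

    # site counts: allocate exact group sizes, hand the largest |ddG|
    # (noisily ranked) to the highest site counts -> mean |ddG| grows with
    # the number of sites
    cnts <- .allocateCounts(n, cf$multi_site_probs)
    noisyRank <- order(abs(ddg) + stats::rnorm(n, 0, 1.5), decreasing = TRUE)
    n_sites <- integer(n)
    offset <- 0L
    for (s in 9:1) {
      if (cnts[s] == 0L) next
      n_sites[noisyRank[(offset + 1):(offset + cnts[s])]] <- s
      offset <- offset + cnts[s]
    }

    # features
    sig <- tanh(ddg / 4)
    sdSig <- stats::sd(sig)
    Z <- matrix(stats::rnorm(n * N_FEATURES), n, N_FEATURES)
    for (j in cf$signal_features) {
      noise <- stats::rnorm(n, 0, cf$noise_scale * sdSig)
      Z[, j] <- as.numeric(scale(sig + noise))
    }
    Y <- apply(Z, 2L, function(col)
      vapply(col, midrankPercentile, numeric(1), x = col))
    X <- cbind(Z, Y)
    colnames(X) <- paste0("z", seq_len(ENCODED_DIM))

    perm <- sample.int(n)
    data <- data.frame(
      protein_id = paste0("P", 1 + (seq_len(n) %% cf$n_proteins)),
      mutation_spec = NA_character_,
      ddg = ddg, n_sites = n_sites, X,
      check.names = FALSE, stringsAsFactors = FALSE)[perm, , drop = FALSE]
    rownames(data) <- NULL
    list(data = data, manifest = cf)
  })
}

#' Write the standard fixture suite
#'
#' Emits the self-contained fixtures the test suite uses: a 5-residue and a
#' 30-residue toy PDB, a 29-column feature table (computed features of the
#' toy structures), a 500-row and a 3366-row encoded dataset, plus a JSON
#' manifest listing every file with its seed. Regeneration with the same
#' seed is byte-identical.
#'
#' @param dir output directory (created if missing).
#' @param seed integer RNG seed.
#' @param full also write the 3366-row table (default TRUE).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
writeFixtureSuite <- function(dir, seed = 1L, full = TRUE) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create directory ", dir)
  probe <- file.path(dir, ".write-probe")
  ok <- tryCatch({ writeLines("", probe); TRUE }, error = function(e) FALSE)
  if (!ok) stop("directory not writable: ", dir)
  unlink(probe)

  entries <- list()
  emit <- function(file, what, sd) {
    entries[[length(entries) + 1L]] <<- list(file = file, what = what,
                                             seed = sd)
  }

  toy5 <- generateToyStructure(5, seed = childSeed(seed, "toy5"))
  writePDB(toy5, file.path(dir, "toy5.pdb"))
  emit("toy5.pdb", "5-residue toy helix PDB", childSeed(seed, "toy5"))

  toy30 <- generateToyStructure(30, seed = childSeed(seed, "toy30"))
  writePDB(toy30, file.path(dir, "toy30.pdb"))
  emit("toy30.pdb", "30-residue toy helix PDB", childSeed(seed, "toy30"))

  feats <- rbind(toy5 = computeFeatures(toy5), toy30 = computeFeatures(toy30))
  ft <- data.frame(model_id = rownames(feats), feats, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (cn in FEATURE_NAMES) ft[[cn]] <- sprintf("%.17g", ft[[cn]])
  utils::write.table(ft, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  emit("features.tsv", "29-column feature table", seed)

  d500 <- generateDataset(syntheticConfig(n_mutants = 500L,
                                          seed = childSeed(seed, "enc500")))
  writeEncodedDataset(d500$data, file.path(dir, "encoded500.tsv"))
  emit("encoded500.tsv", "500-row synthetic encoded dataset",
       childSeed(seed, "enc500"))

  if (full) {
    d3366 <- generateDataset(syntheticConfig(seed = childSeed(seed, "enc3366")))
    writeEncodedDataset(d3366$data, file.path(dir, "encoded3366.tsv"))
    emit("encoded3366.tsv", "3366-row synthetic encoded dataset",
         childSeed(seed, "enc3366"))
  }

  manifest <- list(seed = as.integer(seed), files = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
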