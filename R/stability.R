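#' Electrostatic model constants
#'
#' Physical constants and empirical coefficients for the screened-Coulomb
#' folding-destabilization model. Defaults correspond to cytoplasmic ionic
#' conditions in water near 37 C, expressed so that all energies come out in
#' units of kT.
#'
#' @param bjerrum_length Bjerrum length \eqn{I_b} in Angstrom: the distance at
#'   which two elementary charges interact with energy kT. Default 7.13.
#' @param inverse_debye Inverse Debye screening length \eqn{\kappa} in
#'   1/Angstrom, setting how strongly salt screens electrostatics.
#'   Default 0.03.
#' @param native_his_fraction Expected protonation (charge) fraction of
#'   histidine in the native state. Default 0.4.
#' @param denatured_his_fraction Expected protonation fraction of histidine in
#'   the denatured state. Default 0.1.
#' @param flory_native,flory_denatured Numeric `c(prefactor, exponent)` pairs
#'   for the Flory scaling laws giving the native and denatured radii of
#'   gyration (Angstrom) as `prefactor * N^exponent` in residue count N.
#' @return A list of class `ox_model_constants`.
#' @export
model_constants <- function(bjerrum_length = 7.13,
                            inverse_debye = 0.03,
                            native_his_fraction = 0.4,
                            denatured_his_fraction = 0.1,
                            flory_native = c(2.24, 0.392),
                            flory_denatured = c(1.927, 0.598)) {
  const <- list(
    bjerrum_length = bjerrum_length,
    inverse_debye = inverse_debye,
    native_his_fraction = native_his_fraction,
    denatured_his_fraction = denatured_his_fraction,
    flory_native = flory_native,
    flory_denatured = flory_denatured
  )
  stopifnot(all(vapply(const, function(x) all(is.finite(x) & x > 0), logical(1))))
  structure(const, class = "ox_model_constants")
}

#' Count charged residues in a protein sequence
#'
#' Tallies positively charged (Arg, Lys), negatively charged (Asp, Glu) and
#' variably charged (His) residues. Case-insensitive. Ambiguity and
#' non-standard codes (B, Z, X, U, O) count as non-charged: the model consumes
#' composition only, so the conservative reading is neutral.
#'
#' @param sequence A character scalar of amino-acid letters, or an
#'   [Biostrings::AAString].
#' @return A list with `c_positive`, `c_negative`, `c_variable` and
#'   `n_residues` (sequence length N).
#' @examples
#' count_charges("RKDEH")  # 2 positive, 2 negative, 1 variable, N = 5
#' @export
count_charges <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1L, !is.na(sequence))
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  list(
    c_positive = sum(aa %in% c("R", "K")),
    c_negative = sum(aa %in% c("D", "E")),
    c_variable = sum(aa == "H"),
    n_residues = length(aa)
  )
}

#' Native and denatured net charge
#'
#' Net charge in elementary-charge units for the native and denatured states.
#' Histidine contributes fractionally, with a different expected protonation
#' in the two states:
#' \deqn{Q_n = C_{pos} + 0.4 C_{var} - C_{neg}, \quad
#'       Q_d = C_{pos} + 0.1 C_{var} - C_{neg}}
#'
#' @param comp A charge composition as returned by [count_charges()], or any
#'   list with `c_positive`, `c_negative`, `c_variable`.
#' @param constants Model constants from [model_constants()].
#' @return A list with `q_native` and `q_denatured`.
#' @export
net_charges <- function(comp, constants = model_constants()) {
  stopifnot(comp$c_positive >= 0, comp$c_negative >= 0, comp$c_variable >= 0)
  list(
    q_native = comp$c_positive + constants$native_his_fraction * comp$c_variable -
      comp$c_negative,
    q_denatured = comp$c_positive + constants$denatured_his_fraction * comp$c_variable -
      comp$c_negative
  )
}

#' Flory-scaling radii of gyration
#'
#' Radii of gyration of the native and denatured states from Flory polymer
#' scaling in the residue count N: the native state is compact (exponent
#' below the ideal-chain 1/2), the denatured state expanded (exponent near
#' the excluded-volume 3/5), so \eqn{R_d > R_n} for every protein longer than
#' a couple of residues.
#'
#' @param n_residues Residue count N (vectorized, all >= 1).
#' @param constants Model constants from [model_constants()].
#' @return A list with `r_native` and `r_denatured` in Angstrom.
#' @export
flory_radii <- function(n_residues, constants = model_constants()) {
  stopifnot(all(n_residues >= 1))
  list(
    r_native = constants$flory_native[1] * n_residues^constants$flory_native[2],
    r_denatured = constants$flory_denatured[1] * n_residues^constants$flory_denatured[2]
  )
}

#' Folding free-energy change from a single charge change
#'
#' Screened-Coulomb (Debye-Hueckel) estimate of the change in folding free
#' energy, in kT, caused by adding (`charge_delta = +1`) or removing
#' (`charge_delta = -1`) one elementary charge — the electrostatic signature
#' of a charge-altering oxidative modification:
#' \deqn{\frac{\Delta\Delta G}{kT} =
#'   \frac{I_b(\pm 2 Q_d + 1)}{2 R_d (1 + \kappa R_d)} -
#'   \frac{I_b(\pm 2 Q_n + 1)}{2 R_n (1 + \kappa R_n)}}
#' The value is signed with the denatured-state term first; a negative value
#' means the perturbation favors the (compact, strongly self-interacting)
#' native state less than the denatured one.
#'
#' @param q_native,q_denatured Net charges (elementary charges); vectorized.
#' @param r_native,r_denatured Radii of gyration (Angstrom), all > 0.
#' @param charge_delta `+1` or `-1`, the sign of the single added/removed
#'   charge.
#' @param constants Model constants from [model_constants()].
#' @return ddG in kT (numeric, same length as the inputs).
#' @export
delta_delta_g <- function(q_native, q_denatured, r_native, r_denatured,
                          charge_delta = 1L,
                          constants = model_constants()) {
  stopifnot(charge_delta %in% c(-1L, 1L), all(r_native > 0), all(r_denatured > 0))
  ib <- constants$bjerrum_length
  kappa <- constants$inverse_debye
  self_energy <- function(q, r) {
    ib * (charge_delta * 2 * q + 1) / (2 * r * (1 + kappa * r))
  }
  self_energy(q_denatured, r_denatured) - self_energy(q_native, r_native)
}

#' Oxidation-destabilization susceptibility of one protein
#'
#' Full per-protein evaluation of the electrostatic model: charge composition,
#' native/denatured net charges and radii, signed ddG for charge gain and
#' charge loss, and an aggregate non-negative susceptibility used by the
#' composite score. Averaging the signed values over the two signs collapses
#' to a charge-independent constant, which cannot reproduce the
#' charge-dependent structure of the susceptibility map; the aggregate
#' therefore combines magnitudes (mean by default).
#'
#' @param sequence Amino-acid sequence (character or AAString); non-empty.
#' @param constants Model constants from [model_constants()].
#' @param aggregation How to combine `|ddg_plus|` and `|ddg_minus|`: one of
#'   `"mean"`, `"max"`, `"plus"`, `"minus"`.
#' @return A list of class `ox_stability` with fields `q_native`,
#'   `q_denatured`, `r_native`, `r_denatured`, `ddg_plus`, `ddg_minus`,
#'   `susceptibility` (kT, >= 0) and `n_residues`.
#' @export
susceptibility <- function(sequence, constants = model_constants(),
                           aggregation = c("mean", "max", "plus", "minus")) {
  aggregation <- match.arg(aggregation)
  comp <- count_charges(sequence)
  if (comp$n_residues == 0L) stop("empty sequence")
  q <- net_charges(comp, constants)
  r <- flory_radii(comp$n_residues, constants)
  ddg_plus <- delta_delta_g(q$q_native, q$q_denatured, r$r_native, r$r_denatured,
                            charge_delta = 1L, constants = constants)
  ddg_minus <- delta_delta_g(q$q_native, q$q_denatured, r$r_native, r$r_denatured,
                             charge_delta = -1L, constants = constants)
  sus <- switch(aggregation,
    mean = mean(c(abs(ddg_plus), abs(ddg_minus))),
    max = max(abs(ddg_plus), abs(ddg_minus)),
    plus = abs(ddg_plus),
    minus = abs(ddg_minus)
  )
  structure(
    list(q_native = q$q_native, q_denatured = q$q_denatured,
         r_native = r$r_native, r_denatured = r$r_denatured,
         ddg_plus = ddg_plus, ddg_minus = ddg_minus,
         susceptibility = sus, n_residues = comp$n_residues),
    class = "ox_stability"
  )
}

#' Stability table for a whole proteome
#'
#' Applies the electrostatic model to every record of a FASTA file (or a named
#' character vector / `AAStringSet` of sequences) and returns one row per
#' protein.
#'
#' @param fasta Path to a FASTA file, or a named character vector /
#'   [Biostrings::AAStringSet].
#' @param constants Model constants from [model_constants()].
#' @param aggregation Passed to [susceptibility()].
#' @return A data.frame with columns `protein_id`, `n_residues`, `q_native`,
#'   `q_denatured`, `r_native`, `r_denatured`, `ddg_plus`, `ddg_minus`,
#'   `susceptibility`.
#' @export
stability_table <- function(fasta, constants = model_constants(),
                            aggregation = "mean") {
  seqs <- read_proteome(fasta)
  rows <- lapply(seq_along(seqs), function(i) {
    s <- susceptibility(seqs[[i]], constants, aggregation)
    data.frame(protein_id = names(seqs)[i], n_residues = s$n_residues,
               q_native = s$q_native, q_denatured = s$q_denatured,
               r_native = s$r_native, r_denatured = s$r_denatured,
               ddg_plus = s$ddg_plus, ddg_minus = s$ddg_minus,
               susceptibility = s$susceptibility,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Coerce FASTA path / AAStringSet / character vector to a named character
# vector of sequences, skipping records that fail to parse.
read_proteome <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    fasta <- Biostrings::readAAStringSet(fasta)
  }
  if (methods::is(fasta, "XStringSet")) {
    fasta <- as.character(fasta)
    # FASTA headers may carry descriptions after the id token
    names(fasta) <- vapply(strsplit(names(fasta), "\\s+"), `[`, character(1), 1L)
  }
  stopifnot(is.character(fasta), !is.null(names(fasta)))
  ok <- !is.na(fasta) & nchar(fasta) > 0L
  if (!all(ok)) {
    warning(sum(!ok), " unparseable/empty FASTA record(s) skipped")
    fasta <- fasta[ok]
  }
  fasta
}

#' Susceptibility map of a proteome
#'
#' Positions every protein in the (net charge, length) plane, attaches its
#' destabilization susceptibility, and summarizes the proteome-wide empirical
#' density with kernel-density quartile level sets — contour levels enclosing
#' 25/50/75% of the proteome mass. Each protein is also flagged for
#' membership in the top susceptibility quartile of the reference proteome.
#'
#' The net-charge axis uses the native-state charge Q_n by default (the
#' physiologically displayed state); switch with `charge_axis`.
#'
#' @param fasta FASTA path, named character vector or `AAStringSet`; at least
#'   4 records are required for quartiles.
#' @param constants Model constants from [model_constants()].
#' @param charge_axis `"native"` or `"denatured"`: which net charge spans the
#'   map's charge axis.
#' @param n_grid Grid size per axis for the 2-D kernel density estimate.
#' @return A list of class `ox_susceptibility_map` with `table` (per-protein
#'   data.frame including `top_quartile`), `density` (a [MASS::kde2d] result
#'   or NULL if degenerate) and `quartile_levels` (density levels enclosing
#'   25/50/75% of mass, or NULL).
#' @export
proteome_map <- function(fasta, constants = model_constants(),
                         charge_axis = c("native", "denatured"),
                         n_grid = 100L) {
  charge_axis <- match.arg(charge_axis)
  tab <- stability_table(fasta, constants)
  if (nrow(tab) < 4L) stop("at least 4 records are required for quartiles")
  tab$net_charge <- if (charge_axis == "native") tab$q_native else tab$q_denatured

  sus_q3 <- stats::quantile(tab$susceptibility, 0.75, names = FALSE)
  tab$top_quartile <- tab$susceptibility > sus_q3

  density <- NULL
  quartile_levels <- NULL
  if (stats::sd(tab$net_charge) > 0 && stats::sd(tab$n_residues) > 0) {
    density <- MASS::kde2d(tab$net_charge, tab$n_residues, n = n_grid)
    # density levels whose superlevel sets hold 25/50/75% of the mass
    cell <- diff(density$x[1:2]) * diff(density$y[1:2])
    z <- sort(as.vector(density$z), decreasing = TRUE)
    cum_mass <- cumsum(z) * cell
    quartile_levels <- vapply(c(0.25, 0.5, 0.75), function(p) {
      z[which.max(cum_mass >= p * cum_mass[length(cum_mass)])]
    }, numeric(1))
    names(quartile_levels) <- c("q25", "q50", "q75")
  } else {
    warning("degenerate (net charge, length) distribution; no density contours")
    tab$top_quartile <- rep(FALSE, nrow(tab))
  }

  keep <- c("protein_id", "net_charge", "n_residues", "susceptibility", "top_quartile")
  tab <- tab[order(tab$protein_id), c(keep, setdiff(names(tab), keep))]
  rownames(tab) <- NULL
  structure(
    list(table = tab, density = density, quartile_levels = quartile_levels),
    class = "ox_susceptibility_map"
  )
}
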