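# Computed descriptor backend (OpenBabel via ChemmineOB).
#
# The table backend (read_compound_table) is authoritative for published
# numbers; this backend computes a best-effort DescriptorSet directly from a
# SMILES string.  pH 7.4 adjustments use a small SMARTS + literature-pKa rule
# table with the Henderson-Hasselbalch relation to pick the major species;
# log S uses the ESOL regression (Delaney 2004, J Chem Inf Comput Sci 44:1000)
# on descriptors already in hand.

#' Options for the computed descriptor backend
#'
#' @param ph pH at which protonation-dependent descriptors are evaluated.
#' @param aromatic_include_h If \code{TRUE} hydrogens enter the
#'   denominator of the aromatic-atom percentage; the default counts
#'   heavy atoms only, the usual convention of descriptor software.
#' @param keep_largest_fragment Multi-fragment SMILES (salts) are reduced
#'   to the largest covalent fragment before computation; the removal is
#'   reported via \code{message()}.
#' @return A named list of options for \code{\link{compute_descriptors}}.
#' @export
descriptor_config <- function(ph = 7.4, aromatic_include_h = FALSE,
                              keep_largest_fragment = TRUE) {
  stopifnot(is.numeric(ph), length(ph) == 1L)
  list(ph = ph, aromatic_include_h = isTRUE(aromatic_include_h),
       keep_largest_fragment = isTRUE(keep_largest_fragment))
}

# SMARTS rule table for ionisable groups. pKa values are textbook class
# averages, not per-molecule predictions; type "acid" loses a proton when
# pH > pKa, "base" gains one when pH < pKa.  dhbd is the change in the
# donor-ATOM count on ionisation (the convention of the HBD descriptor):
# a deprotonated acid oxygen stops donating; a protonated primary or
# secondary amine already donated, so only tertiary amines gain a donor.
.ionisable_rules <- function() {
  data.frame(
    name = c("sulfonic_acid", "carboxylic_acid", "tetrazole",
             "aliphatic_amine_primary", "aliphatic_amine_secondary",
             "aliphatic_amine_tertiary", "amidine_guanidine"),
    smarts = c(
      "[SX4](=O)(=O)[OX2H1]",
      "[CX3](=O)[OX2H1]",
      "[cX3]1[nX2][nX2][nX2][nX3H1]1",
      "[NX3;H2;!$([NX3][CX3]=[OX1,SX1,NX2]);!$([NX3][a]);!$([NX3][SX4])]",
      "[NX3;H1;!$([NX3][CX3]=[OX1,SX1,NX2]);!$([NX3][a]);!$([NX3][SX4])]",
      "[NX3;H0;!$([NX3][CX3]=[OX1,SX1,NX2]);!$([NX3][a]);!$([NX3][SX4]);!$([NX3+])]",
      "[NX3][CX3](=[NX2])[NX3]"),
    type = c("acid", "acid", "acid", "base", "base", "base", "base"),
    pka = c(-1.0, 4.8, 4.9, 10.6, 10.7, 10.0, 12.5),
    dhbd = c(-1L, -1L, -1L, 0L, 0L, 1L, 0L),
    stringsAsFactors = FALSE)
}

.require_ob <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop(errorCondition(
      "the computed backend needs the ChemmineOB package; use the table backend instead",
      class = c("hl_backend_error", "hl_error")))
  }
}

# parse one SMILES into an OpenBabel molecule reference, or error
.parse_smiles <- function(smiles) {
  .require_ob()
  mols <- try(suppressWarnings(
    ChemmineOB::forEachMol("SMILES", paste(smiles, "mol"), identity)),
    silent = TRUE)
  ok <- !inherits(mols, "try-error") && length(mols) >= 1L
  if (ok) {
    n_heavy <- try(ChemmineOB::smartsSearch_OB(mols[1], "[!#1]",
                                               uniqueMatches = FALSE),
                   silent = TRUE)
    ok <- !inherits(n_heavy, "try-error") && n_heavy > 0
  }
  if (!ok) {
    stop(errorCondition(paste0("unparseable structure: ", dQuote(smiles)),
                        class = c("hl_parse_error", "hl_error")))
  }
  mols[1]
}

.smarts_count <- function(mol, smarts) {
  as.numeric(ChemmineOB::smartsSearch_OB(mol, smarts, uniqueMatches = FALSE))
}

# hydrogens from a Hill formula string such as "C6H5NO2"
.formula_h_count <- function(formula) {
  m <- regmatches(formula, regexec("H([0-9]*)([A-Z]|$)", formula))[[1]]
  if (length(m) < 2L) return(0L)
  if (m[2] == "") 1L else as.integer(m[2])
}

#' Compute the ten descriptors from a SMILES string
#'
#' The computed backend: parses the structure with OpenBabel, reduces
#' salts to the largest covalent fragment, computes molar mass, log P,
#' topological PSA, rotatable bonds and aromatic-atom percentage, then
#' derives the pH-dependent fields (formal charge, H-bond donor and
#' acceptor counts, log D) for the major species at \code{config$ph}
#' using a SMARTS/pKa rule table and the Henderson-Hasselbalch relation.
#' log S is estimated with the ESOL regression. Deterministic for a
#' fixed \code{config}.
#'
#' @param smiles A single SMILES string.
#' @param config Backend options from \code{\link{descriptor_config}}.
#' @return A complete descriptor set (named list, see
#'   \code{\link{as_descriptor_set}}).
#' @export
#' @examples
#' \dontrun{
#' compute_descriptors("c1ccccc1")          # benzene: aromatic_pct 100
#' compute_descriptors("CC(=O)O")           # acetate at pH 7.4: charge -1
#' }
compute_descriptors <- function(smiles, config = descriptor_config()) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  .require_ob()

  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0L) {
    stop(errorCondition(paste0("unparseable structure: ", dQuote(smiles)),
                        class = c("hl_parse_error", "hl_error")))
  }
  if (length(frags) > 1L) {
    if (!config$keep_largest_fragment) {
      stop(errorCondition(
        paste0("multi-fragment structure and keep_largest_fragment = FALSE: ",
               dQuote(smiles)),
        class = c("hl_parse_error", "hl_error")))
    }
    sizes <- vapply(frags, function(f)
      .smarts_count(.parse_smiles(f), "[!#1]"), numeric(1))
    keep <- which.max(sizes)
    message("multi-fragment structure; keeping largest fragment ",
            dQuote(frags[keep]), ", dropping ",
            paste(dQuote(frags[-keep]), collapse = ", "))
    smiles <- frags[keep]
  }

  mol <- .parse_smiles(smiles)
  props <- ChemmineOB::prop_OB(mol)

  n_heavy <- .smarts_count(mol, "[!#1]")
  n_arom <- .smarts_count(mol, "[a]")
  denom <- n_heavy
  if (config$aromatic_include_h) denom <- denom + .formula_h_count(props$formula)
  aromatic_pct <- 100 * n_arom / denom
  # symmetric two-atom SMARTS: every bond matched in both directions
  rotors <- .smarts_count(mol, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]") / 2

  # charge explicitly drawn in the SMILES (e.g. quaternary N+)
  q_explicit <- .smarts_count(mol, "[*+]") + 2 * .smarts_count(mol, "[*+2]") -
    .smarts_count(mol, "[*-]") - 2 * .smarts_count(mol, "[*-2]")

  rules <- .ionisable_rules()
  dq <- 0L          # protonation-state charge adjustment
  dhbd <- 0L        # donor-count adjustment
  logd_corr <- 0    # Henderson-Hasselbalch log D correction, summed per site
  ph <- config$ph
  for (k in seq_len(nrow(rules))) {
    hits <- .smarts_count(mol, rules$smarts[k])
    if (hits == 0) next
    if (rules$type[k] == "acid") {
      if (ph > rules$pka[k]) {   # deprotonated major species
        dq <- dq - as.integer(hits)
        dhbd <- dhbd + as.integer(hits) * rules$dhbd[k]
      }
      logd_corr <- logd_corr - hits * log10(1 + 10^(ph - rules$pka[k]))
    } else {
      if (ph < rules$pka[k]) {   # protonated major species
        dq <- dq + as.integer(hits)
        dhbd <- dhbd + as.integer(hits) * rules$dhbd[k]
      }
      logd_corr <- logd_corr - hits * log10(1 + 10^(rules$pka[k] - ph))
    }
  }

  logp <- props$logP
  logd74 <- logp + logd_corr
  hbd74 <- max(0L, as.integer(props$HBD) + dhbd)
  hba74 <- as.integer(props$HBA1)
  formal_charge74 <- as.integer(round(q_explicit)) + dq

  # ESOL estimate; aromatic proportion enters as a fraction of heavy atoms
  logs <- 0.16 - 0.63 * logp - 0.0062 * props$MW + 0.066 * rotors -
    0.74 * (n_arom / n_heavy)

  as_descriptor_set(list(
    molar_mass = props$MW, aromatic_pct = aromatic_pct, psa = props$TPSA,
    logd74 = logd74, logs = logs, logp = logp,
    rotatable_bonds = as.integer(round(rotors)), hba74 = hba74,
    hbd74 = hbd74, formal_charge74 = formal_charge74))
}
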