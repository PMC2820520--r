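## Reaction network: species, per-reaction fluxes, stoichiometry and the
## time derivative. A pure-R evaluator is the canonical, documented surface;
## src/tcs_deriv.c carries an equivalent compiled version used by the
## integrator (their agreement is enforced in the test suite).

.TCS_SPECIES <- c("mRNA_tcs", "mRNA_ds", "SHK", "SHKP", "RR", "RRP",
                  "C_t", "C_p", "RRP2", "DS")

## names of the 22 model reactions (Table-1-style lumped view)
.TCS_REACTIONS <- c(
  "r1_txn_tcs_regulated", "r2_txn_ds_regulated",
  "r3_txn_tcs_basal", "r4_txn_ds_basal",
  "r5_mrna_decay", "r6_tsn_shk", "r7_tsn_rr", "r8_tsn_ds",
  "r9_protein_dilution", "r10_autophosphorylation",
  "r11_autodephosphorylation", "r12_bind_shk_rrp", "r13_bind_shkp_rr",
  "r14_phosphotransfer", "r15_reverse_phosphotransfer",
  "r16_dissoc_shk_rrp", "r17_dissoc_shkp_rr", "r18_phosphatase",
  "r19_exogenous_phosphorylation", "r20_exogenous_dephosphorylation",
  "r21_dimerization", "r22_undimerization"
)

## expanded elementary reactions: row 5 split per mRNA, row 9 per protein
.TCS_REACTIONS_EXPANDED <- c(
  .TCS_REACTIONS[1:4],
  paste0("r5_decay_", c("mRNA_tcs", "mRNA_ds")),
  .TCS_REACTIONS[6:8],
  paste0("r9_dilution_", .TCS_SPECIES[3:10]),
  .TCS_REACTIONS[10:22]
)

#' Species names of the model
#'
#' The ten molecular species tracked by the model, in state-vector order:
#' the two mRNAs (TCS operon, downstream operon), free sensor kinase
#' \code{SHK}/\code{SHKP}, free response regulator \code{RR}/\code{RRP}, the
#' two enzyme-substrate complexes \code{C_t} (SHK.RRP) and \code{C_p}
#' (SHKP.RR), the transcriptionally active phospho-dimer \code{RRP2}, and a
#' downstream reporter protein \code{DS}.
#'
#' @return character vector of length 10.
#' @export
tcsSpecies <- function() .TCS_SPECIES

#' Construct a state vector
#'
#' @param ... named concentrations (\eqn{\mu}M); unspecified species are 0.
#' @return named numeric vector over \code{tcsSpecies()}.
#' @export
tcsState <- function(...) {
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) &&
      length(vals[[1]]) == length(.TCS_SPECIES)) {
    s <- as.numeric(vals[[1]])
    names(s) <- .TCS_SPECIES
    return(s)
  }
  unknown <- setdiff(names(vals), .TCS_SPECIES)
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "))
  s <- stats::setNames(numeric(length(.TCS_SPECIES)), .TCS_SPECIES)
  s[names(vals)] <- unlist(vals)
  s
}

#' Derived totals of a state
#'
#' \code{SHK_tot = SHK + SHKP + C_t + C_p};
#' \code{RR_tot = RR + RRP + C_t + C_p + 2 RRP2};
#' \code{RRP_tot = RRP + C_t + 2 RRP2} (total phosphorylated response
#' regulator: free RRP, RRP held in the phosphatase complex, and the dimer).
#'
#' @param state a state vector or a trajectory matrix with species columns.
#' @return named vector (or matrix) with \code{SHK_tot}, \code{RR_tot},
#'   \code{RRP_tot}.
#' @export
speciesTotals <- function(state) {
  g <- function(nm) if (is.matrix(state)) state[, nm] else state[[nm]]
  cbindOrC <- if (is.matrix(state)) cbind else c
  out <- cbindOrC(
    SHK_tot = g("SHK") + g("SHKP") + g("C_t") + g("C_p"),
    RR_tot  = g("RR") + g("RRP") + g("C_t") + g("C_p") + 2 * g("RRP2"),
    RRP_tot = g("RRP") + g("C_t") + 2 * g("RRP2"))
  out
}

## parameter vector handed to both the R and the C evaluator
.parmVector <- function(params, topology, k_ph = params$k_ph,
                        k_ap = params$k_ap) {
  variant_code <- match(topology$variant,
                        c("wild_type", "open_loop", "no_feedback",
                          "circuit_I", "circuit_II")) - 1L
  c(k_ap = k_ap, k_ad = params$k_ad, k_ph = k_ph,
    k_b = params$k_b, k_d = params$k_d, k_b1 = params$k_b1,
    k_d1 = params$k_d1, k_pt = params$k_pt, k_tp = params$k_tp,
    k_RRPdm = params$k_RRPdm, k_RRPmd = params$k_RRPmd,
    k_txn = params$k_txn, k_txnbasal = params$k_txnbasal,
    K_m = params$K_m, K_mDS = params$K_mDS,
    k_SKtsn = params$k_SKtsn, tsn_mult = params$tsn_mult,
    k_mRNAdeg = params$k_mRNAdeg,
    k_exp = params$k_exp, K_mexp = params$K_mexp,
    k_exd = params$k_exd, K_mexd = params$K_mexd,
    k_dil = params$k_dil,
    variant = variant_code,
    R0 = topology$R0 %||% 0,
    const_tcs_txn = topology$const_tcs_txn %||% 0,
    const_shk_txn = topology$const_shk_txn %||% 0,
    const_rr_txn = topology$const_rr_txn %||% 0)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

.mm <- function(vmax, km, s) vmax * pmax(s, 0) / (km + pmax(s, 0))

## expanded elementary fluxes (length 30) from a raw state + parm vector;
## internal hot path shared by reactionFluxes and timeDerivative
.fluxesExpanded <- function(y, pv) {
  mT <- y[[1]]; mD <- y[[2]]; SHK <- y[[3]]; SHKP <- y[[4]]; RR <- y[[5]]
  RRP <- y[[6]]; Ct <- y[[7]]; Cp <- y[[8]]; R2 <- y[[9]]; DS <- y[[10]]
  variant <- pv[[24]]
  A1 <- if (variant == 1) pv[[25]] else R2
  v1 <- if (variant == 2) pv[[26]] else .mm(pv[[12]], pv[[14]], A1)
  v3 <- if (variant == 2) 0 else pv[[13]]
  c(v1,
    .mm(pv[[12]], pv[[15]], R2),                      # r2
    v3,
    pv[[13]],                                         # r4
    pv[[18]] * mT, pv[[18]] * mD,                     # r5 (per mRNA)
    if (variant == 3) pv[[27]] else pv[[16]] * mT,    # r6
    if (variant == 4) pv[[28]] else pv[[17]] * pv[[16]] * mT,  # r7
    pv[[16]] * mD,                                    # r8
    pv[[23]] * c(SHK, SHKP, RR, RRP, Ct, Cp, R2, DS), # r9 (per protein)
    pv[[1]] * SHK,                                    # r10
    pv[[2]] * SHKP,                                   # r11
    pv[[4]] * SHK * RRP,                              # r12
    pv[[6]] * SHKP * RR,                              # r13
    pv[[8]] * Cp,                                     # r14
    pv[[9]] * Ct,                                     # r15
    pv[[5]] * Ct,                                     # r16
    pv[[7]] * Cp,                                     # r17
    pv[[3]] * Ct,                                     # r18
    .mm(pv[[19]], pv[[20]], RR),                      # r19
    .mm(pv[[21]], pv[[22]], RRP),                     # r20
    pv[[10]] * RRP * RRP,                             # r21
    pv[[11]] * R2)                                    # r22
}

## derivative from the expanded flux vector (avoids forming S %*% v in the
## hot path; algebra mirrors stoichiometryMatrix exactly and the test suite
## checks the identity)
.rhs <- function(y, pv) {
  v <- .fluxesExpanded(y, pv)
  c(v[1] + v[3] - v[5],
    v[2] + v[4] - v[6],
    v[7] - v[18] + v[19] - v[20] + v[24] + v[26] - v[10],
    v[18] - v[19] - v[21] + v[25] - v[11],
    v[8] - v[21] + v[25] + v[26] - v[27] + v[28] - v[12],
    -v[20] + v[24] + v[27] - v[28] - 2 * v[29] + 2 * v[30] - v[13],
    v[20] + v[22] - v[23] - v[24] - v[26] - v[14],
    v[21] - v[22] + v[23] - v[25] - v[15],
    v[29] - v[30] - v[16],
    v[9] - v[17])
}

.checkState <- function(state) {
  if (length(state) != length(.TCS_SPECIES))
    stop("state must have ", length(.TCS_SPECIES), " entries")
  if (any(!is.finite(state))) stop("state must be finite")
  if (any(state < 0))
    stop("negative concentration(s) in state")
  state
}

#' Per-reaction fluxes
#'
#' Evaluates the rate law of every model reaction at a state. In the default
#' (lumped, length-22) view the pooled mRNA-decay and protein-dilution rows
#' report total loss fluxes; \code{expanded = TRUE} returns the 30 elementary
#' fluxes (decay and dilution split per species) that satisfy
#' \code{timeDerivative = stoichiometryMatrix(expanded = TRUE) \%*\% fluxes}.
#'
#' Rate laws: regulated transcription is saturating in the phospho-dimer,
#' \eqn{k_{txn}[RRP_2]/(K + [RRP_2])} with \eqn{K = K_m} for the TCS operon
#' (replaced by the exogenous regulator \eqn{R_0} under the open-loop
#' variant) and \eqn{K = K_{mDS}} downstream; exogenous
#' (de)phosphorylation of free RR(P) is Michaelis-Menten; everything else is
#' mass action.
#'
#' @param state nonnegative state vector over \code{tcsSpecies()}.
#' @param params a \code{tcs_params} object.
#' @param topology a \code{tcs_topology} (default wild type).
#' @param k_ph,k_ap signal values overriding the ones in \code{params}.
#' @param expanded return the 30 elementary fluxes instead of the 22
#'   reaction-row totals.
#' @return named numeric vector of nonnegative fluxes (\eqn{\mu}M/s).
#' @export
reactionFluxes <- function(state, params, topology = makeTopology("wild_type"),
                           k_ph = params$k_ph, k_ap = params$k_ap,
                           expanded = FALSE) {
  .checkState(state)
  .checkTopology(topology)
  pv <- .parmVector(params, topology, k_ph = k_ph, k_ap = k_ap)
  v <- .fluxesExpanded(state, pv)
  if (expanded) return(stats::setNames(v, .TCS_REACTIONS_EXPANDED))
  lumped <- c(v[1:4], sum(v[5:6]), v[7:9], sum(v[10:17]), v[18:30])
  stats::setNames(lumped, .TCS_REACTIONS)
}

#' Time derivative of the state
#'
#' Mass-balance right-hand side: stoichiometry times elementary fluxes.
#' Every protein, complex, and the dimer carries a \code{-k_dil} growth
#' dilution term; both mRNAs decay at \code{k_mRNAdeg}.
#'
#' @inheritParams reactionFluxes
#' @return named numeric vector \code{d(state)/dt} (\eqn{\mu}M/s).
#' @export
timeDerivative <- function(state, params,
                           topology = makeTopology("wild_type"),
                           k_ph = params$k_ph, k_ap = params$k_ap) {
  .checkState(state)
  .checkTopology(topology)
  pv <- .parmVector(params, topology, k_ph = k_ph, k_ap = k_ap)
  stats::setNames(.rhs(state, pv), .TCS_SPECIES)
}

#' Stoichiometry matrix
#'
#' @param expanded if \code{TRUE} (default), the 10 x 30 matrix over the
#'   elementary reactions, for which \code{derivative = S \%*\% fluxes} holds
#'   exactly; if \code{FALSE}, the 10 x 22 reaction-row view in which the
#'   pooled decay/dilution columns mark affected species with -1 (a summary of
#'   connectivity, not usable in the product identity).
#' @return integer matrix, rows = species, columns = reactions.
#' @export
stoichiometryMatrix <- function(expanded = TRUE) {
  rx <- if (expanded) .TCS_REACTIONS_EXPANDED else .TCS_REACTIONS
  S <- matrix(0L, nrow = length(.TCS_SPECIES), ncol = length(rx),
              dimnames = list(.TCS_SPECIES, rx))
  put <- function(r, sp, coef) S[sp, r] <<- coef
  put("r1_txn_tcs_regulated", "mRNA_tcs", 1L)
  put("r3_txn_tcs_basal", "mRNA_tcs", 1L)
  put("r2_txn_ds_regulated", "mRNA_ds", 1L)
  put("r4_txn_ds_basal", "mRNA_ds", 1L)
  put("r6_tsn_shk", "SHK", 1L)
  put("r7_tsn_rr", "RR", 1L)
  put("r8_tsn_ds", "DS", 1L)
  if (expanded) {
    put("r5_decay_mRNA_tcs", "mRNA_tcs", -1L)
    put("r5_decay_mRNA_ds", "mRNA_ds", -1L)
    for (sp in .TCS_SPECIES[3:10])
      put(paste0("r9_dilution_", sp), sp, -1L)
  } else {
    S[c("mRNA_tcs", "mRNA_ds"), "r5_mrna_decay"] <- -1L
    S[.TCS_SPECIES[3:10], "r9_protein_dilution"] <- -1L
  }
  put("r10_autophosphorylation", "SHK", -1L)
  put("r10_autophosphorylation", "SHKP", 1L)
  put("r11_autodephosphorylation", "SHKP", -1L)
  put("r11_autodephosphorylation", "SHK", 1L)
  put("r12_bind_shk_rrp", "SHK", -1L)
  put("r12_bind_shk_rrp", "RRP", -1L)
  put("r12_bind_shk_rrp", "C_t", 1L)
  put("r13_bind_shkp_rr", "SHKP", -1L)
  put("r13_bind_shkp_rr", "RR", -1L)
  put("r13_bind_shkp_rr", "C_p", 1L)
  put("r14_phosphotransfer", "C_p", -1L)
  put("r14_phosphotransfer", "C_t", 1L)
  put("r15_reverse_phosphotransfer", "C_t", -1L)
  put("r15_reverse_phosphotransfer", "C_p", 1L)
  put("r16_dissoc_shk_rrp", "C_t", -1L)
  put("r16_dissoc_shk_rrp", "SHK", 1L)
  put("r16_dissoc_shk_rrp", "RRP", 1L)
  put("r17_dissoc_shkp_rr", "C_p", -1L)
  put("r17_dissoc_shkp_rr", "SHKP", 1L)
  put("r17_dissoc_shkp_rr", "RR", 1L)
  put("r18_phosphatase", "C_t", -1L)
  put("r18_phosphatase", "SHK", 1L)
  put("r18_phosphatase", "RR", 1L)
  put("r19_exogenous_phosphorylation", "RR", -1L)
  put("r19_exogenous_phosphorylation", "RRP", 1L)
  put("r20_exogenous_dephosphorylation", "RRP", -1L)
  put("r20_exogenous_dephosphorylation", "RR", 1L)
  put("r21_dimerization", "RRP", -2L)
  put("r21_dimerization", "RRP2", 1L)
  put("r22_undimerization", "RRP2", -1L)
  put("r22_undimerization", "RRP", 2L)
  S
}
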