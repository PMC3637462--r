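#' Health-state space of the colorectal neoplasia model
#'
#' The model follows individuals from normal colorectal epithelium through
#' the adenoma-carcinoma sequence to death.  Adenomas are split into
#' low-risk (<10 mm) and intermediate/high-risk (>=10 mm) classes;
#' colorectal cancer (CRC) is split into preclinical (asymptomatic,
#' screen-detectable) and clinical (diagnosed) compartments, each staged
#' I-IV.  Post-polypectomy states mark persons whose adenomas were removed
#' at screening (no longer eligible for invitation; the
#' intermediate/high-risk group is under surveillance colonoscopy).
#' `CancerCare` holds long-term survivors of treated CRC.  The two death
#' states are absorbing.
#'
#' @return Character vector of the 16 state labels, in canonical order.
#' @export
health_states <- function() {
  c("Normal",
    "AdenomaLowRisk", "AdenomaIntHighRisk",
    "PreclinicalCRC_I", "PreclinicalCRC_II", "PreclinicalCRC_III",
    "PreclinicalCRC_IV",
    "ClinicalCRC_I", "ClinicalCRC_II", "ClinicalCRC_III", "ClinicalCRC_IV",
    "SurveillanceLowRisk", "SurveillanceIntHighRisk",
    "CancerCare",
    "CRCDeath", "OtherDeath")
}

# Canonical index helpers (fixed order; used throughout internal code).
.S <- local({
  s <- c("Normal",
         "AdenomaLowRisk", "AdenomaIntHighRisk",
         "PreclinicalCRC_I", "PreclinicalCRC_II", "PreclinicalCRC_III",
         "PreclinicalCRC_IV",
         "ClinicalCRC_I", "ClinicalCRC_II", "ClinicalCRC_III",
         "ClinicalCRC_IV",
         "SurveillanceLowRisk", "SurveillanceIntHighRisk",
         "CancerCare",
         "CRCDeath", "OtherDeath")
  structure(as.list(seq_along(s)), names = s)
})

#' State labels by role
#'
#' @return `absorbing_states()`: the two absorbing death states.
#'   `invitable_states()`: states whose occupants are alive, undiagnosed
#'   and therefore eligible to be invited for screening.
#'   `diagnosed_states()`: alive states whose occupants have had an
#'   adenoma or CRC diagnosis and are no longer invited.
#' @export
absorbing_states <- function() c("CRCDeath", "OtherDeath")

#' @rdname absorbing_states
#' @export
invitable_states <- function() {
  c("Normal", "AdenomaLowRisk", "AdenomaIntHighRisk",
    "PreclinicalCRC_I", "PreclinicalCRC_II", "PreclinicalCRC_III",
    "PreclinicalCRC_IV")
}

#' @rdname absorbing_states
#' @export
diagnosed_states <- function() {
  c("ClinicalCRC_I", "ClinicalCRC_II", "ClinicalCRC_III", "ClinicalCRC_IV",
    "SurveillanceLowRisk", "SurveillanceIntHighRisk", "CancerCare")
}

.stages <- c("I", "II", "III", "IV")
.preclin <- paste0("PreclinicalCRC_", c("I", "II", "III", "IV"))
.clinical <- paste0("ClinicalCRC_", c("I", "II", "III", "IV"))
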