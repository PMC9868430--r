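#' @importFrom stats aggregate anova as.formula coef kmeans lm logLik pchisq
#'   quantile rbinom rlnorm rnorm runif setNames rexp sd var update vcov
#'   rmultinom AIC pnorm format.pval complete.cases
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

# Ethogram vocabulary ---------------------------------------------------------

#' Ethogram labels
#'
#' Label sets for the six sow postures and the three standing activities.
#' Postures: `ST` standing, `SI` sitting, `K` kneeling, `SL` sternal lying,
#' `LL` lateral lying (udder hidden), `LLU` lateral lying with the udder
#' exposed. Activities (defined only while standing): `EAT`, `DRINK`, `OTHER`.
#'
#' @format Character vectors.
#' @name ethogram
NULL

#' @rdname ethogram
#' @export
POSTURES <- c("ST", "SI", "K", "SL", "LL", "LLU")

#' @rdname ethogram
#' @export
LYING_POSTURES <- c("SL", "LL", "LLU")

#' @rdname ethogram
#' @export
ACTIVITIES <- c("EAT", "DRINK", "OTHER")

#' Default posture merge map
#'
#' Sitting and kneeling are visually confounded classes and are pooled into a
#' single `SIK` class for all analyses; other labels map to themselves. The
#' map can be replaced wholesale (e.g. an identity map) in
#' [merge_postures()].
#'
#' @return Named character vector mapping ethogram labels to analysis labels.
#' @export
default_merge_map <- function() {
  c(ST = "ST", SI = "SIK", K = "SIK", SL = "SL", LL = "LL", LLU = "LLU")
}

#' Merged analysis posture classes (default map)
#' @rdname ethogram
#' @export
MERGED_POSTURES <- c("ST", "SIK", "SL", "LL", "LLU")

# Transition sets for posture-change counting (on merged labels).
# Crushing-risk: standing -> any lying, and sternal -> lateral (udder
# exposed or not). Nursing-stop: udder-exposed lateral lying -> anything.
.RISK_CRUSH_FROM <- c("ST", "ST", "ST", "SL", "SL")
.RISK_CRUSH_TO   <- c("LL", "LLU", "SL", "LL", "LLU")

# Internal validation helpers -------------------------------------------------

.assert_postures <- function(x, vocab = POSTURES, what = "posture") {
  bad <- setdiff(unique(x), vocab)
  if (length(bad)) {
    stop(sprintf("unknown %s label(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)
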