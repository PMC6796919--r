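#' Evaluated relation classes
#'
#' The five CHEMPROT relation groups used for evaluation, preceded by the
#' abstention class `"NEGATIVE"`. The class order is fixed across the whole
#' package: the negative class sits at index 1, which the decision-threshold
#' rule relies on (see [tune_threshold()]).
#'
#' @return Character vector
#'   `c("NEGATIVE", "CPR:3", "CPR:4", "CPR:5", "CPR:6", "CPR:9")`.
#' @export
#' @examples
#' cpr_classes()
cpr_classes <- function() {
  c(NEGATIVE_LABEL, CPR_POSITIVE)
}

NEGATIVE_LABEL <- "NEGATIVE"
CPR_POSITIVE <- c("CPR:3", "CPR:4", "CPR:5", "CPR:6", "CPR:9")

# Placeholder tokens used for entity blinding.
CHEM_PLACEHOLDER <- "#chemical"
GENE_PLACEHOLDER <- "#gene"
PAIR_PLACEHOLDER <- "#chemical#gene"
NONE_LABEL <- "#none"

# Fixed representation sizes: up to 10 tokens (9 hops) on the shortest
# dependency path, 20 tokens per context sequence, 4 context sequences.
SDP_MAX_LEN <- 10L
CTX_MAX_LEN <- 20L
LIN_LEN <- 4L * CTX_MAX_LEN
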