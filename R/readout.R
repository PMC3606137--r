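# The eight-neuron readout bank and its differential signals.  The bank
# mirrors the standard congruent/incongruent split: two congruent neurons
# per congruent quadrant (up/far, down/near) feed both tasks; each
# incongruent quadrant (down/far, up/near) contributes one neuron to the
# depth readout and one to the direction readout.

#' Specification of the eight-neuron readout bank
#'
#' @return A data frame with columns `neuron` (1-8), `pref_dir`,
#'   `pref_depth`, `congruent` (logical) and `contributes`
#'   ("both"/"direction"/"depth").
#' @export
bank_spec <- function() {
  data.frame(
    neuron = 1:8,
    pref_dir = c("up", "up", "down", "down", "up", "up", "down", "down"),
    pref_depth = c("far", "far", "far", "far", "near", "near", "near",
                   "near"),
    congruent = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    contributes = c("both", "both", "depth", "direction", "depth",
                    "direction", "both", "both"),
    stringsAsFactors = FALSE
  )
}

# Differential readout coefficients.  Congruent responses are halved so
# each side of a difference carries one incongruent and two half-weight
# congruent neurons:
#   i_dir = [(s1+s2)/2 + s6] - [(s7+s8)/2 + s4]
#   i_dep = [(s1+s2)/2 + s3] - [(s7+s8)/2 + s5]
DIR_COEF <- c(0.5, 0.5, 0, -1, 0, 1, -0.5, -0.5)
DEP_COEF <- c(0.5, 0.5, 1, 0, -1, 0, -0.5, -0.5)

#' Rate series of the eight bank neurons for one stimulus
#'
#' Each bank neuron reads the population table at the stimulus strengths
#' flipped into its own preference frame: a neuron preferring "down"
#' sees `-C_dir`, a neuron preferring "near" sees `-C_dep`.  No
#' interpolation: the (absolute) strengths must be grid levels.
#'
#' @param table A [population_rate_table()].
#' @param C_dir,C_dep Signed stimulus strengths (up/far positive).
#' @param task "direction" or "depth" (selects the task slice of the
#'   table).
#' @return A numeric matrix (time bins x 8 neurons) of rates in
#'   spikes/ms.
#' @export
bank_rates <- function(table, C_dir, C_dep, task) {
  spec <- bank_spec()
  out <- matrix(0, length(table$tau), 8L)
  for (n in 1:8) {
    cd <- if (spec$pref_dir[n] == "up") C_dir else -C_dir
    cp <- if (spec$pref_depth[n] == "far") C_dep else -C_dep
    out[, n] <- table_rate(table, cd, cp, task)
  }
  colnames(out) <- paste0("n", 1:8)
  out
}

#' Instantaneous differential direction and depth signals
#'
#' Combines the eight bank spike trains into the two signed evidence
#' streams, halving the congruent neurons' responses:
#' `i_dir = (s1+s2)/2 + s6 - (s7+s8)/2 - s4` and
#' `i_dep = (s1+s2)/2 + s3 - (s7+s8)/2 - s5`.  With 0/1 spike
#' indicators both signals lie in \[-2, 2\] spikes/ms.
#'
#' @param spikes A matrix (time bins x 8) of 0/1 spike indicators, or a
#'   list of eight aligned [spike_train()] objects (bank order).
#' @return A list of class `differential_signals` with numeric vectors
#'   `i_dir` and `i_dep` (spikes/ms) on the common time grid.
#' @export
differential_signals <- function(spikes) {
  if (is.list(spikes) && !is.matrix(spikes)) {
    lens <- vapply(spikes, function(t) length(t$bins), integer(1))
    if (length(spikes) != 8L || length(unique(lens)) != 1L) {
      stop("need eight aligned spike trains", call. = FALSE)
    }
    spikes <- vapply(spikes, function(t) as.numeric(t$bins),
                     numeric(lens[1]))
  }
  if (!is.matrix(spikes) || ncol(spikes) != 8L) {
    stop("`spikes` must be a (time x 8) matrix", call. = FALSE)
  }
  structure(
    list(i_dir = drop(spikes %*% DIR_COEF),
         i_dep = drop(spikes %*% DEP_COEF)),
    class = "differential_signals"
  )
}
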