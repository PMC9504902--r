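#' Evidence accumulation state
#'
#' Exponential smoothing of per-window class probabilities:
#' `P*(t) = alpha_s P*(t-1) + (1 - alpha_s) p_t`, starting from the
#' uninformative prior `p0 = 0.5`. A trial decision is issued as soon as the
#' accumulated evidence for either class exceeds the certainty threshold.
#'
#' @param alpha_s Smoothing factor; 0.95 or 0.96 in practice.
#' @param threshold Certainty threshold, usually chosen in `[0.70, 0.85]`.
#' @param p0 Initial accumulated probability.
#' @return A list of class `evidence_state`.
#' @export
evidence_state <- function(alpha_s = 0.95, threshold = 0.75, p0 = 0.5) {
  stopifnot(alpha_s >= 0, alpha_s <= 1, threshold > 0.5, threshold <= 1,
            p0 >= 0, p0 <= 1)
  structure(list(alpha_s = alpha_s, threshold = threshold, p0 = p0),
            class = "evidence_state")
}

#' Accumulate per-window probabilities into a trial decision
#'
#' Applies the smoothing recursion window by window. The decision is the
#' class whose evidence (`P*` for class 1, `1 - P*` for class 0) first
#' exceeds the threshold, with the crossing index recorded. If neither
#' crosses within the trial, the decision falls back to the side of the
#' final `P*` relative to 0.5 and is flagged as a timeout, so an accuracy is
#' defined for every trial.
#'
#' @param p_seq Per-window probabilities of class 1, each in `[0, 1]`.
#' @param state An [evidence_state()].
#' @return A list of class `evidence_decision`: `decision` (0/1),
#'   `crossed_at` (window index, `NA` on timeout), `timeout` (flag),
#'   `trajectory` (the `P*` sequence, bounded in `[0, 1]`).
#' @export
accumulate_evidence <- function(p_seq, state = evidence_state()) {
  if (length(p_seq) == 0) stop("empty probability sequence", call. = FALSE)
  if (any(p_seq < 0 | p_seq > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  a <- state$alpha_s
  P <- numeric(length(p_seq))
  cur <- state$p0
  decision <- NA_integer_
  crossed_at <- NA_integer_
  for (t in seq_along(p_seq)) {
    cur <- a * cur + (1 - a) * p_seq[t]
    P[t] <- cur
    if (is.na(crossed_at)) {
      if (cur >= state$threshold) {
        decision <- 1L; crossed_at <- t
      } else if (1 - cur >= state$threshold) {
        decision <- 0L; crossed_at <- t
      }
    }
  }
  timeout <- is.na(crossed_at)
  if (timeout) decision <- as.integer(P[length(P)] > 0.5)
  structure(list(decision = decision, crossed_at = crossed_at,
                 timeout = timeout, trajectory = P),
            class = "evidence_decision")
}

#' @export
print.evidence_decision <- function(x, ...) {
  cat("<evidence_decision> class ", x$decision,
      if (x$timeout) " (timeout)" else paste0(" at window ", x$crossed_at),
      ", final P* = ", signif(x$trajectory[length(x$trajectory)], 4),
      "\n", sep = "")
  invisible(x)
}
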