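# Typed error conditions, so callers can distinguish structural model
# failures (curves that never cross, transplant arm that never catches up)
# from ordinary bad input.

stop_txbenefit <- function(class, message, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "txbenefit_error"),
                      call = call))
}

stop_no_crossing <- function() {
  stop_txbenefit("txbenefit_no_crossing",
    paste("survival curves never intersect: excess transplant hazard",
          "persists (final-period relative risk >= 1)"))
}

stop_no_catchup <- function() {
  stop_txbenefit("txbenefit_no_catchup",
    paste("transplant arm never accumulates as many life years as the",
          "wait-list arm: no time of equal cumulative life years exists"))
}

stop_no_equivalence <- function(msg) {
  stop_txbenefit("txbenefit_no_equivalence", msg)
}
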