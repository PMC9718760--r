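# Built-in calibration self-test: puckering conventions, the exhaustive
# 38-conformer roundtrip, and the six predicted-mass checkpoints.

#' Run the package calibration self-test
#'
#' Checks that (i) an ideal 4C1 chair gives theta = 0 and the canonical
#' O,3B boat gives theta = 90, phi = 0; (ii) the construct -> transform ->
#' classify roundtrip is the identity for all 38 canonical conformers at
#' several amplitudes; and (iii) the six reference predicted masses of the
#' native and 4-thio single-addition/co-polymerisation products are
#' reproduced within 0.01 Da.
#'
#' @param verbose print a line per check group.
#' @return TRUE invisibly if all checks pass, otherwise stops.
#' @export
selftest <- function(verbose = TRUE) {
  say <- function(...) if (verbose) message(...)

  st <- cremer_pople(canonical_ring("4C1", 0.57))
  stopifnot(abs(st$theta) < 1e-6)
  st <- cremer_pople(canonical_ring("1C4", 0.57))
  stopifnot(abs(st$theta - 180) < 1e-6)
  st <- cremer_pople(canonical_ring("O,3B", 0.76))
  stopifnot(abs(st$theta - 90) < 1e-6,
            min(st$phi, 360 - st$phi) < 1e-6)
  say("pucker convention calibration: ok")

  tab <- conformer_table()
  for (Q in c(0.35, 0.57, 0.76)) {
    for (k in seq_len(nrow(tab))) {
      got <- classify_conformer(cremer_pople(canonical_ring(tab$name[k], Q)))
      if (!identical(got$name, tab$name[k])) {
        stop("roundtrip failure: ", tab$name[k], " at Q=", Q,
             " classified as ", got$name)
      }
    }
  }
  say("38-conformer roundtrip: ok")

  expect <- rbind(
    c(950.29, 966.27), c(1329.40, 1361.36), c(1708.51, 1756.44))
  for (k in 0:2) {
    mn <- predicted_mz(addition_product(k, thio = FALSE))
    ms <- predicted_mz(addition_product(k, thio = TRUE))
    stopifnot(abs(mn - expect[k + 1, 1]) <= 0.01,
              abs(ms - expect[k + 1, 2]) <= 0.01)
  }
  say("predicted-mass checkpoints: ok")
  invisible(TRUE)
}
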