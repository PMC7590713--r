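# Element data used by the parser, molecular-weight computation and the
# curation rules. Average (not monoisotopic) atomic masses, IUPAC 2021.

.ocsr_masses <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.065,
  Cl = 35.453, K = 39.098, Ca = 40.078, Fe = 55.845, Cu = 63.546, Zn = 65.38,
  Se = 78.971, Br = 79.904, I = 126.904, Li = 6.94, Sn = 118.71, As = 74.922
)

# Valence lists for implicit-hydrogen assignment (Daylight convention:
# lowest listed valence that is >= the current bond-order sum).
.ocsr_valences <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L, Se = c(2L, 4L, 6L)
)

# Organic subset: atoms writable without brackets.
.ocsr_organic <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.ocsr_aromatic_ok <- c("C", "N", "O", "P", "S", "Se", "B")

# Elements admitted by curation rule R3.
.ocsr_allowed_elements <- c("C", "H", "O", "N", "P", "S", "F", "Cl", "Br",
                            "I", "Se", "B")

.ocsr_element_mass <- function(elem) {
  m <- .ocsr_masses[elem]
  if (anyNA(m)) {
    stop(ocsr_condition("ocsr_parse_error",
      paste0("unknown element mass: ", paste(elem[is.na(m)], collapse = ", "))))
  }
  unname(m)
}

#' Construct a classed ocsr condition
#'
#' All recoverable failures in the package (parse failures, invalid structure
#' strings, render failures, contract violations) are signalled as classed
#' conditions so callers can count them without string matching.
#'
#' @param class condition subclass, e.g. "ocsr_parse_error"
#' @param message human-readable message
#' @param ... further fields stored on the condition
#' @return a condition object inheriting from `class`, "ocsr_error", "error"
#' @keywords internal
ocsr_condition <- function(class, message, ...) {
  structure(
    class = c(class, "ocsr_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}
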