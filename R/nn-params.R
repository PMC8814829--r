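# Nearest-neighbor free-energy parameters for RNA duplexes (37 C,
# kcal/mol), Turner 2004 set: Watson-Crick stacks from Xia et al. 1998,
# G.U wobble stacks from Mathews et al. 1999, as tabulated in the
# parameter files distributed with common RNA secondary-structure
# software. The loop model here is deliberately simple: length-dependent
# bulge and interior-loop initiation with a capped asymmetry (NINIO)
# term; no terminal-mismatch or special small-loop tables.

PAIR_TYPES <- c("CG", "GC", "GU", "UG", "AU", "UA")

# stack[p1, p2]: energy of pair p2 stacked 3' of pair p1 on the top
# strand, i.e. duplex 5'-t1 t2-3' / 3'-b1 b2-5' with p1 = t1:b1,
# p2 = t2:b2
NN_STACK <- matrix(c(
  # CG     GC     GU     UG     AU     UA      <- p2
  -3.30, -2.40, -1.40, -2.10, -2.10, -2.10,   # p1 = CG
  -3.40, -3.30, -1.50, -2.50, -2.40, -2.20,   # p1 = GC
  -2.50, -2.10, -0.50,  1.30, -1.30, -1.40,   # p1 = GU
  -1.50, -1.40,  0.30, -0.50, -1.00, -0.60,   # p1 = UG
  -2.20, -2.10, -0.60, -1.40, -0.90, -1.10,   # p1 = AU
  -2.40, -2.10, -1.00, -1.30, -1.30, -0.90),  # p1 = UA
  nrow = 6, byrow = TRUE, dimnames = list(PAIR_TYPES, PAIR_TYPES))

NN_BULGE <- c(3.80, 2.80, 3.20, 3.60, 4.00, 4.40, 4.60, 4.70, 4.80, 4.90,
              5.00, 5.10, 5.20, 5.30, 5.40, 5.40, 5.50, 5.50, 5.60, 5.70,
              5.70, 5.80, 5.80, 5.80, 5.90, 5.90, 6.00, 6.00, 6.00, 6.10)

NN_INTERNAL <- c(NA, 1.00, 1.00, 1.10, 2.00, 2.00, 2.10, 2.30, 2.40, 2.50,
                 2.60, 2.70, 2.80, 2.90, 2.90, 3.00, 3.10, 3.10, 3.20, 3.30,
                 3.30, 3.40, 3.40, 3.50, 3.50, 3.50, 3.60, 3.60, 3.70, 3.70)

NN_MISC <- list(duplex_init = 4.10, terminal_au = 0.50,
                ninio_m = 0.60, ninio_max = 3.00)

#' Nearest-neighbor duplex parameter table
#'
#' Returns the embedded free-energy parameter set used by
#' [duplex_energy()] so that callers (and tests) can recompute energies
#' by direct table summation.
#'
#' @return list with `stack` (6x6 matrix over pair types CG, GC, GU,
#'   UG, AU, UA; `stack[p1, p2]` is the energy of stacking pair p2 on
#'   pair p1 along the top strand), `bulge` and `internal` (loop
#'   initiation by loop length 1..30), `duplex_init`, `terminal_au`
#'   (penalty per helix end closed by an AU or GU pair), `ninio_m` /
#'   `ninio_max` (interior-loop asymmetry), and a `provenance` note.
#' @export
nn_parameters <- function() {
  list(stack = NN_STACK, bulge = NN_BULGE, internal = NN_INTERNAL,
       duplex_init = NN_MISC$duplex_init,
       terminal_au = NN_MISC$terminal_au,
       ninio_m = NN_MISC$ninio_m, ninio_max = NN_MISC$ninio_max,
       provenance = paste(
         "Turner 2004 RNA nearest-neighbor set (Xia et al. 1998 WC stacks;",
         "Mathews et al. 1999 wobble stacks); simplified loop model"))
}

# pair type of top-strand base a against bottom-strand base b (DNA
# letters, T plays U); NA if not a canonical or wobble pair
pair_type_code <- function(a, b) {
  key <- paste0(a, b)
  unname(c(CG = 1L, GC = 2L, GT = 3L, TG = 4L, AT = 5L, TA = 6L)[key])
}
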