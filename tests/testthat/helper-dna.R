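# Hand-built configurations realizing the DNA model's milestone states.
# Geometry: template anchored on the x axis (promoter sites 1,2 then bases
# A,C,T,G at spacing 2); everything else placed far away unless docked.

dna_stage_config <- function(stage = c("apart", "docked", "AU", "AUCG",
                                       "complete")) {
  stage <- match.arg(stage)
  x <- matrix(0, 20, 2)
  x[1, ] <- c(0, 0);  x[2, ] <- c(2, 0)            # promoter
  x[5, ] <- c(4, 0);  x[6, ] <- c(6, 0)            # bases A C
  x[7, ] <- c(8, 0);  x[8, ] <- c(10, 0)           # bases T G
  far <- function(k) c(30 + 6 * k, 25)             # parked far away
  x[3, ] <- far(1); x[4, ] <- far(1) + c(2, 0)     # polymerase
  nuc <- list(U = 9:11, G = 12:14, A = 15:17, C = 18:20)
  for (k in seq_along(nuc)) {
    ids <- nuc[[k]]
    x[ids[1], ] <- far(k + 1)
    x[ids[2], ] <- far(k + 1) + c(1, 0)
    x[ids[3], ] <- far(k + 1) + c(2, 0)
  }
  dock_pol <- function(x) {
    x[3, ] <- c(0, 2); x[4, ] <- c(2, 2); x
  }
  # dock nucleotide under its template base; the sugar/phosphate tail leans
  # away so that backbone pairs of adjacent docked nucleotides stay outside
  # the bond-formed radius until closed explicitly
  dock_nuc <- function(x, ids, base_x) {
    x[ids[1], ] <- c(base_x, -2)
    x[ids[2], ] <- c(base_x - 0.7, -2.7)
    x[ids[3], ] <- c(base_x - 1.4, -3.4)
    x
  }
  if (stage %in% c("docked", "AU", "AUCG", "complete")) x <- dock_pol(x)
  if (stage %in% c("AU", "AUCG", "complete")) x <- dock_nuc(x, 9:11, 4)
  if (stage %in% c("AUCG", "complete")) x <- dock_nuc(x, 12:14, 6)
  if (stage == "complete") {
    x <- dock_nuc(x, 15:17, 8)
    x <- dock_nuc(x, 18:20, 10)
    # close the backbone: phosphate of each nucleotide onto the next sugar
    x[11, ] <- x[13, ] + c(-1, 0)   # U phos next to G sugar
    x[14, ] <- x[16, ] + c(-1, 0)
    x[17, ] <- x[19, ] + c(-1, 0)
  }
  x
}
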