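DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degeneracy sets; used for PAM-pattern scoring and genome validation
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# pairwise compatibility (non-empty intersection of degeneracy sets)
COMPAT_MAT <- local({
  codes <- names(IUPAC_SETS)
  m <- matrix(FALSE, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (a in codes) {
    for (b in codes) {
      m[a, b] <- length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0
    }
  }
  m
})
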