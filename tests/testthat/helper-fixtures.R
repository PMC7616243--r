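# shared small fixtures, built in code at test time

# a small lateral-scar phantom used by several files
smallScarSpec <- function(seed = 7, burden = 0.3, imageSize = 128L,
                          nSlices = 6L) {
  phantomSpec(imageSize = imageSize, nSlices = nSlices,
              scarPresent = c(septal = FALSE, lateral = TRUE),
              scarBurden = c(septal = 0, lateral = burden), seed = seed)
}

# a clean annular slice with RV crescent, built directly from masks
annularSlice <- function(sz = 96, rEndo = 18, rEpi = 30, rvArc = 100,
                         scarPx = integer(0)) {
  ctr <- sz / 2
  X <- matrix(rep(seq_len(sz) - ctr, each = sz), sz, sz)
  Y <- matrix(rep(seq_len(sz) - ctr, times = sz), sz, sz)
  R <- sqrt(X^2 + Y^2); TH <- atan2(Y, X)
  endo <- (R <= rEndo) * 1
  epi <- (R <= rEpi) * 1
  rv <- ((R > rEpi) & (R <= rEpi + 8) & (abs(TH) <= rvArc * pi / 360)) * 1
  scar <- matrix(0, sz, sz)
  scar[scarPx] <- 1
  img <- matrix(-50, sz, sz); img[epi == 1] <- 120; img[endo == 1] <- 400
  sliceRecord(img, endo, epi, rv, scar)
}

# brute-force AUC by counting concordant positive-negative pairs
pairCountAUC <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
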