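## Small internal helpers.

## Run code under a fixed RNG seed without disturbing the caller's RNG
## stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

randomDNA <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## Vectorized reverse complement on character vectors.
revComp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

## Normalize matrix columns to sum to 1e6 (TPM convention). All-zero
## columns are left at zero with a warning.
normalizeTPM <- function(mat) {
  cs <- colSums(mat)
  zero <- cs == 0
  if (any(zero)) {
    warning("column(s) with zero total abundance left at zero: ",
            paste(colnames(mat)[zero], collapse = ", "))
    cs[zero] <- 1
  }
  sweep(mat, 2, cs, "/") * 1e6
}

padId <- function(prefix, i, width = 4L) {
  sprintf(paste0(prefix, "%0", width, "d"), i)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## Split a nucleotide string into codons for a given frame offset
## (0, 1, 2); trailing partial codons are dropped.
frameCodons <- function(seq, frame) {
  n <- nchar(seq)
  starts <- seq.int(1L + frame, n - 2L, by = 3L)
  if (n - frame < 3L) return(character(0))
  substring(seq, starts, starts + 2L)
}
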