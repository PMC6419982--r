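# Internal helpers shared across modules.

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

randomDNA <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Substitute bases at given positions with a uniformly chosen *different*
# base; `seq` a single string.
mutateBases <- function(seq, positions) {
  if (!length(positions)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Character matrix (rows = sequences) from equal-length strings.
seqCharMatrix <- function(x) {
  if (!length(x)) return(matrix(character(0), nrow = 0))
  matrix(unlist(strsplit(x, ""), use.names = FALSE),
         nrow = length(x), byrow = TRUE)
}

cleanRefSequence <- function(x) {
  x <- toupper(x)
  x <- gsub("[.\\-~ ]", "", x)
  chartr("U", "T", x)
}
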