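# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations do not perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# One global seed fans out to per-stage child seeds by fixed offsets so that
# pipeline stages are independently reproducible. Kept below 2^31.
.stage_offsets <- c(
  genome = 11L, insertions = 23L, methylation = 37L, fragments = 41L,
  subsample = 53L, controls = 67L, folds = 79L, shuffle = 89L,
  split = 97L, pipeline = 101L
)

child_seed <- function(seed, stage) {
  stopifnot(stage %in% names(.stage_offsets))
  (abs(as.integer(seed)) %% 1000000L) * 1000L + .stage_offsets[[stage]]
}

.BASES <- c("A", "C", "G", "T")

# ASCII lookup table: byte -> base index 1..4, NA otherwise (N etc.)
.base_code_table <- local({
  tab <- rep(NA_integer_, 256L)
  tab[utf8ToInt("A")] <- 1L
  tab[utf8ToInt("C")] <- 2L
  tab[utf8ToInt("G")] <- 3L
  tab[utf8ToInt("T")] <- 4L
  tab
})

# Encode one DNA string as integer codes (NA for non-ACGT).
base_codes <- function(seq) {
  .base_code_table[utf8ToInt(seq)]
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All 4^k k-mers in lexicographic order (first character slowest), matching
# the base-4 column indices of encode_kmer().
all_kmers <- function(k) {
  g <- expand.grid(rep(list(.BASES), k), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  do.call(paste0, g[k:1])  # expand.grid varies the first column fastest
}

# Sum counts of identical (contig, pos, strand) site rows.
aggregate_sites <- function(sites) {
  if (nrow(sites) == 0) return(sites)
  key <- paste(sites$contig, sites$pos, sites$strand, sep = "\r")
  cnt <- rowsum(as.numeric(sites$count), key)
  first <- !duplicated(key)
  out <- sites[first, c("contig", "pos", "strand"), drop = FALSE]
  out$count <- as.integer(round(cnt[match(key[first], rownames(cnt)), 1L]))
  sort_sites(out)
}

sort_sites <- function(sites) {
  out <- sites[order(sites$contig, sites$pos, sites$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_sites <- function(contig = character(), pos = integer(),
                      strand = character(), count = integer()) {
  data.frame(contig = as.character(contig), pos = as.integer(pos),
             strand = as.character(strand), count = as.integer(count),
             stringsAsFactors = FALSE)
}

#' Merge site strands
#'
#' Collapses insertion sites to strand-merged per-position counts; all
#' counting operations in the package work on strand-merged signal.
#'
#' @param sites insertion-site data frame (`contig`, `pos`, `strand`, `count`).
#' @return a site data frame with strand set to `"*"`.
#' @export
merge_site_strands <- function(sites) {
  if (nrow(sites) == 0) return(new_sites())
  s <- sites
  s$strand <- "*"
  aggregate_sites(s)
}
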