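# Interval conventions: every internal interval is 0-based half-open on the
# transcript-oriented ("local") genome. Conversion to/from 1-based inclusive
# GFF3 disk coordinates happens only in the GFF3 reader/writer.

# tibble(start, end) -> IRanges (1-based inclusive)
as_iranges0 <- function(iv) {
  IRanges::IRanges(start = iv$start + 1L, end = iv$end)
}

iranges_to_tbl0 <- function(ir) {
  tibble::tibble(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

interval_widths <- function(iv) iv$end - iv$start

# set difference a \ b on 0-based half-open interval tables
interval_setdiff <- function(a, b) {
  if (nrow(a) == 0L) return(tibble::tibble(start = integer(), end = integer()))
  if (nrow(b) == 0L) return(a)
  iranges_to_tbl0(IRanges::setdiff(as_iranges0(a), as_iranges0(b)))
}

validate_intervals <- function(iv, what = "intervals") {
  if (nrow(iv) == 0L) abort(paste0(what, ": empty interval set"))
  if (any(iv$end <= iv$start)) abort(paste0(what, ": zero or negative width"))
  if (nrow(iv) > 1L) {
    o <- order(iv$start)
    if (!identical(o, seq_len(nrow(iv)))) abort(paste0(what, ": not sorted"))
    if (any(iv$start[-1L] < iv$end[-nrow(iv)])) {
      abort(paste0(what, ": overlapping segments"))
    }
  }
  invisible(iv)
}

# Greek form labels in alphabet order, with ascii twins for plain reports.
GREEK_GLYPHS <- c(
  "α", "β", "γ", "δ", "ε", "ζ", "η",
  "θ", "ι", "κ", "λ", "μ", "ν", "ξ",
  "ο", "π", "ρ", "σ", "τ", "υ", "φ",
  "χ", "ψ", "ω"
)
GREEK_NAMES <- c(
  "alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta", "theta",
  "iota", "kappa", "lambda", "mu", "nu", "xi", "omicron", "pi", "rho",
  "sigma", "tau", "upsilon", "phi", "chi", "psi", "omega"
)

greek_label <- function(i) {
  # cycles with a numeric suffix past omega; i is 1-based (1 = alpha)
  n <- length(GREEK_GLYPHS)
  cycle <- (i - 1L) %/% n
  pos <- (i - 1L) %% n + 1L
  list(
    glyph = paste0(GREEK_GLYPHS[pos], ifelse(cycle > 0L, cycle + 1L, "")),
    ascii = paste0(GREEK_NAMES[pos], ifelse(cycle > 0L, cycle + 1L, ""))
  )
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

random_dna <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
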