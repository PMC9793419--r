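#' Validate a coding sequence
#'
#' Checks that a nucleotide string is a well-formed CDS: alphabet
#' `{A, C, G, T}`, length a multiple of 3, and no internal stop codon (a
#' terminal stop is allowed).
#'
#' @param nt Nucleotide string.
#' @return The validated uppercase string (class `coding_sequence`).
#' @export
coding_sequence <- function(nt) {
  nt <- toupper(as.character(nt)[1])
  if (!grepl("^[ACGT]*$", nt)) stopf("sequence error: characters outside {A,C,G,T}")
  if (nchar(nt) == 0L || nchar(nt) %% 3L != 0L)
    stopf("sequence error: length %d is not a positive multiple of 3", nchar(nt))
  aa <- translate_codons(split_codons(nt))
  if (any(aa[-length(aa)] == "*"))
    stopf("sequence error: internal stop codon at codon %d",
          which(aa[-length(aa)] == "*")[1])
  structure(nt, class = "coding_sequence")
}

split_codons <- function(nt) {
  substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
}

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Load a codon usage table
#'
#' Reads a per-codon usage table (columns `codon`, `per_1000`) and normalizes
#' the weights within each synonymous family so they sum to 1. The bundled
#' default is a representative genome-wide \emph{C. elegans} usage table
#' (approximate per-1000 frequencies compiled from published codon-usage
#' tables); supply your own CSV for other organisms.
#'
#' @param path CSV path; default the bundled \emph{C. elegans} table.
#' @return Named numeric vector of 64 within-family relative usage weights.
#' @export
codon_usage_table <- function(path = system.file("extdata",
                                                 "celegans_codon_usage.csv",
                                                 package = "memfish")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "per_1000") %in% names(tab)))
    stopf("codon usage table needs columns codon, per_1000")
  w <- setNames(as.numeric(tab$per_1000), toupper(tab$codon))
  if (!setequal(names(w), names(Biostrings::GENETIC_CODE)))
    stopf("codon usage table must cover all 64 codons")
  aa <- Biostrings::GENETIC_CODE[names(w)]
  for (fam in unique(aa)) {
    i <- which(aa == fam)
    s <- sum(w[i])
    w[i] <- if (s > 0) w[i] / s else 1 / length(i)
  }
  w
}

#' Synonymously re-code a CDS for maximum nucleotide divergence
#'
#' Replaces every codon with the synonymous codon that is most different at
#' the nucleotide level while keeping the encoded protein identical — the
#' strategy behind re-coded transgenes whose mRNA can be distinguished from
#' the endogenous transcript by hybridization probes. For each codon, among
#' the synonymous codons whose within-family usage weight is at least
#' `min_usage` (the usage floor keeps expression-unfriendly rare codons out),
#' the codon with the maximum Hamming distance to the original is chosen;
#' ties break toward higher usage, then alphabetically. Stop codons are only
#' ever exchanged within the stop family. The rule is fully deterministic:
#' `seed` is reserved for a future stochastic mode and affects nothing.
#'
#' @param cds CDS string or `coding_sequence`.
#' @param usage Named usage-weight vector from [codon_usage_table()].
#' @param min_usage Usage floor within each family (default 0.05).
#' @param seed Ignored (deterministic rule); kept for interface stability.
#' @return A `coding_sequence` translating to exactly the same protein.
#' @examples
#' recode_cds("ATGTGG")          # Met-Trp: single-codon families, unchanged
#' identity_aa("ATGCTT", recode_cds("ATGCTT"))  # always 100
#' @export
recode_cds <- function(cds, usage = codon_usage_table(), min_usage = 0.05,
                       seed = NULL) {
  cds <- coding_sequence(cds)
  codons <- split_codons(unclass(cds))
  aa_all <- Biostrings::GENETIC_CODE
  fam_by_aa <- split(names(aa_all), aa_all)
  out <- vapply(codons, function(cod) {
    fam <- fam_by_aa[[aa_all[[cod]]]]
    allowed <- fam[usage[fam] >= min_usage]
    if (length(allowed) == 0L)
      stopf("min_usage %.3g leaves no allowed codon for family %s",
            min_usage, aa_all[[cod]])
    hd <- vapply(allowed, function(a) hamming_codon(a, cod), integer(1))
    cand <- allowed[hd == max(hd)]
    if (length(cand) > 1L) {
      u <- usage[cand]
      cand <- cand[u == max(u)]
      cand <- sort(cand)[1]
    }
    cand
  }, character(1), USE.NAMES = FALSE)
  coding_sequence(paste(out, collapse = ""))
}

hamming_codon <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Percent nucleotide identity between equal-length sequences
#'
#' @param a,b Nucleotide strings of equal length.
#' @return Percent of matching positions (0–100).
#' @export
identity_nt <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) != nchar(b)) stopf("comparison error: lengths differ (%d vs %d)",
                                  nchar(a), nchar(b))
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  100 * sum(ca == cb) / length(ca)
}

#' Percent amino-acid identity between equal-length coding sequences
#'
#' Translates both sequences with the standard codon table and compares
#' residues positionally.
#'
#' @param a,b CDS strings of equal length (valid reading frames).
#' @return Percent of matching residues (0–100).
#' @export
identity_aa <- function(a, b) {
  a <- coding_sequence(a); b <- coding_sequence(b)
  if (nchar(a) != nchar(b)) stopf("comparison error: lengths differ")
  pa <- translate_codons(split_codons(unclass(a)))
  pb <- translate_codons(split_codons(unclass(b)))
  100 * sum(pa == pb) / length(pa)
}

#' Longest run of consecutive matching nucleotides
#'
#' Positional comparison of equal-length sequences; the longest stretch of
#' consecutive matches proxies the longest probe-sized region a hybridization
#' probe could not distinguish.
#'
#' @param a,b Nucleotide strings of equal length.
#' @return Integer run length.
#' @export
longest_shared_run <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) != nchar(b)) stopf("comparison error: lengths differ")
  m <- strsplit(a, "")[[1]] == strsplit(b, "")[[1]]
  if (!any(m)) return(0L)
  r <- rle(m)
  max(r$lengths[r$values])
}

#' Generate a random CDS without internal stops
#'
#' Utility for simulations and property tests: uniform random codons drawn
#' from the 61 sense codons, with an optional terminal stop.
#'
#' @param n_codons Number of sense codons.
#' @param seed Integer seed.
#' @param terminal_stop Append a TAA stop codon?
#' @return A `coding_sequence`.
#' @export
random_cds <- function(n_codons, seed = 1L, terminal_stop = FALSE) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  with_seed(seed, {
    body <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
    coding_sequence(if (terminal_stop) paste0(body, "TAA") else body)
  })
}
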