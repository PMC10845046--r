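# Heuristic assignment of concrete DNA bases to abstract domains, with
# cross-talk screening and FASTA export.  The circuits are designed at the
# domain level; this stage only has to produce sequences that respect the
# declared complementarities and avoid unintended complementary runs.

BASES <- c("A", "C", "G", "T")

revcomp_chr <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(seq, "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), ""))
}

base_domain_table <- function(crn, toehold_len, domain_len) {
  rows <- list()
  for (s in crn$strands) {
    for (d in s$domains) {
      nm <- sub("\\*$", "", d$name)
      if (is.null(rows[[nm]]))
        rows[[nm]] <- list(name = nm, kind = d$kind,
                           length = if (d$kind == "toehold") toehold_len
                                    else domain_len)
    }
  }
  do.call(rbind, lapply(rows, function(r)
    data.frame(name = r$name, kind = r$kind, length = r$length,
               stringsAsFactors = FALSE)))
}

# Canonical-orientation rule: a window is admissible iff it is strictly
# smaller (A<C<G<T, position-wise) than its reverse complement.  For any
# non-palindromic k-mer exactly one of {k, revcomp(k)} is admissible and
# palindromes are admissible never, so if every window of every domain is
# admissible, no k-mer and its reverse complement can both occur anywhere in
# the pool -- unintended complementary runs of >= k nt are excluded by
# construction, at any number of domains.
window_admissible <- function(w) {
  a <- utf8ToInt(w)
  b <- utf8ToInt(revcomp_chr(w))
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] < 0
}

sample_domain_seq <- function(len, gc_range, alphabet, max_run = 6) {
  for (i in 1:500) {
    chars <- character(len)
    ok <- TRUE
    for (pos in seq_len(len)) {
      placed <- FALSE
      for (b in sample(alphabet)) {
        if (pos >= max_run) {
          w <- paste(c(chars[(pos - max_run + 1):(pos - 1)], b),
                     collapse = "")
          if (!window_admissible(w)) next
        }
        chars[pos] <- b
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }   # dead end: restart the domain
    }
    if (!ok) next
    seq <- paste(chars, collapse = "")
    gc <- mean(chars %in% c("G", "C"))
    if (gc >= gc_range[1] && gc <= gc_range[2]) return(seq)
  }
  stop("could not sample a domain sequence within the GC range", call. = FALSE)
}

kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

# A cross-talk violation is a pair of base domains d1, d2 (possibly d1 == d2)
# such that some k-mer of d1 is the reverse complement of a k-mer of d2.
# Intended pairings (a domain with its own complement) never enter the scan
# because only base-domain sequences are compared.
crosstalk_pairs <- function(seqs, k) {
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (nm in names(seqs)) {
    for (km in unique(kmers(seqs[[nm]], k))) {
      index[[km]] <- c(index[[km]], nm)
    }
  }
  hits <- list()
  for (nm in names(seqs)) {
    for (km in unique(kmers(seqs[[nm]], k))) {
      partners <- index[[revcomp_chr(km)]]
      for (p in partners)
        hits[[length(hits) + 1L]] <- c(nm, p)
    }
  }
  unique(hits)
}

#' Assign DNA sequences to the domains of a compiled circuit
#'
#' Seeded rejection sampling under a canonical-orientation constraint: every
#' `max_run`-nucleotide window of every base domain must be strictly smaller
#' than its reverse complement, which excludes unintended complementary runs
#' of `max_run` nt or more between non-partner domains by construction (no
#' k-mer and its reverse complement can both occur in the pool).  Complement
#' domains map to reverse complements and GC content is held inside
#' `gc_range`.  A k-mer screen then verifies the pool and resamples any
#' offender (none are expected under the constraint).
#'
#' @param crn A compiled `dsd_crn` (its strand registry defines the domains).
#' @param toehold_len,domain_len Domain lengths in nucleotides.
#' @param gc_range Allowed GC fraction per domain.
#' @param max_run Forbidden complementary-run length between non-partner
#'   domains (nt).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @param three_letter_toeholds If `TRUE`, toeholds use the A/C/T alphabet.
#' @param max_retries Resampling rounds before giving up.
#' @return A `dsd_seqs` object: data.frame `domains` (name, kind, length,
#'   seq) plus the design settings.
#' @export
assign_sequences <- function(crn, toehold_len = 6, domain_len = 15,
                             gc_range = c(0.3, 0.7), max_run = 6, seed = 1,
                             three_letter_toeholds = FALSE,
                             max_retries = 200) {
  stopifnot(inherits(crn, "dsd_crn"))
  tab <- base_domain_table(crn, toehold_len, domain_len)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  alphabet_for <- function(kind) {
    if (kind == "toehold" && three_letter_toeholds) c("A", "C", "T") else BASES
  }
  seqs <- stats::setNames(
    mapply(function(len, kind) sample_domain_seq(len, gc_range,
                                                 alphabet_for(kind), max_run),
           tab$length, tab$kind),
    tab$name)
  for (round in seq_len(max_retries)) {
    bad <- crosstalk_pairs(seqs, max_run)
    if (length(bad) == 0) {
      tab$seq <- unname(seqs[tab$name])
      return(structure(list(domains = tab, seed = seed,
                            toehold_len = toehold_len,
                            domain_len = domain_len, gc_range = gc_range,
                            max_run = max_run),
                       class = "dsd_seqs"))
    }
    # resample the second member of each violating pair
    for (pair in bad) {
      nm <- pair[2]
      kind <- tab$kind[tab$name == nm][1]
      seqs[[nm]] <- sample_domain_seq(tab$length[tab$name == nm][1], gc_range,
                                      alphabet_for(kind), max_run)
    }
  }
  bad <- crosstalk_pairs(seqs, max_run)
  stop(sprintf("sequence design failed after %d rounds; unresolved cross-talk between domains '%s' and '%s'",
               max_retries, bad[[1]][1], bad[[1]][2]), call. = FALSE)
}

#' @export
print.dsd_seqs <- function(x, ...) {
  cat(sprintf("sequence assignment: %d domains (toehold %d nt, long %d nt, seed %d)\n",
              nrow(x$domains), x$toehold_len, x$domain_len, x$seed))
  invisible(x)
}

domain_sequence <- function(assignment, name) {
  base <- sub("\\*$", "", name)
  i <- match(base, assignment$domains$name)
  if (is.na(i))
    stop("incomplete assignment: no sequence for domain ", name, call. = FALSE)
  s <- assignment$domains$seq[i]
  if (endsWith(name, "*")) revcomp_chr(s) else s
}

#' Full base sequence of one elementary strand
#'
#' @param assignment A `dsd_seqs` from [assign_sequences()].
#' @param strand A strand record from `crn$strands`.
#' @return A single DNA string (5' to 3' concatenation of its domains).
#' @export
strand_sequence <- function(assignment, strand) {
  paste(vapply(strand$domains, function(d)
    domain_sequence(assignment, d$name), ""), collapse = "")
}

#' Write every elementary strand of a circuit to FASTA
#'
#' One record per distinct elementary strand; the record name is the
#' strand's canonical id and the sequence is the concatenation of its
#' assigned domain sequences.
#'
#' @param assignment A `dsd_seqs`.
#' @param crn The compiled circuit the assignment was made for.
#' @param path Output FASTA path.
#' @return Invisibly, the number of records written.
#' @export
write_fasta <- function(assignment, crn, path) {
  stopifnot(inherits(assignment, "dsd_seqs"), inherits(crn, "dsd_crn"))
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("the Biostrings package is required for FASTA export", call. = FALSE)
  seqs <- vapply(crn$strands, function(s) strand_sequence(assignment, s), "")
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(crn$strands)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(length(set))
}
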