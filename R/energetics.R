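## Nearest-neighbour energetics of guide:target RNA duplexes.
## Coordinates are 1-based on the guide, 5'->3'. By assay convention the
## guide's first nucleotide (g1) is anchored in the MID-domain pocket and is
## never part of the paired span, so spans start at g2.

.RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")

.check_rna <- function(seq, what = "sequence") {
  s <- toupper(gsub("T", "U", seq))
  ch <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(ch), names(.RNA_COMP))
  if (length(bad)) {
    stop(what, " contains non-RNA characters: ",
         paste(bad, collapse = ", "))
  }
  s
}

#' An RNA guide (piRNA)
#'
#' @param sequence Guide sequence 5'->3' over A/C/G/U (T is accepted and
#'   converted). Length must be in 10-40 nt.
#' @param three_prime_2ome Logical; guide carries a 3'-terminal 2'-O-methyl.
#'   Treated as thermodynamically neutral (methylated and unmethylated guides
#'   behave identically in cleavage assays); recorded for provenance only.
#' @return An object of class `rna_guide`.
#' @export
rna_guide <- function(sequence, three_prime_2ome = FALSE) {
  s <- .check_rna(sequence, "guide")
  n <- nchar(s)
  if (n < 10L || n > 40L) {
    stop("guide length must be between 10 and 40 nt (got ", n, ")")
  }
  structure(list(sequence = s, length = n,
                 three_prime_2ome = isTRUE(three_prime_2ome)),
            class = "rna_guide")
}

#' A contiguous paired span on the guide
#'
#' @param g_start,g_end 1-based inclusive guide positions of the contiguous
#'   Watson-Crick paired run. By convention `g_start = 2`.
#' @param guide_length Optional guide length for bounds checking.
#' @return An object of class `paired_span`.
#' @export
paired_span <- function(g_start, g_end, guide_length = NULL) {
  stopifnot(g_start >= 1L, g_end >= g_start)
  if (!is.null(guide_length) && g_end > guide_length) {
    stop("span end exceeds guide length")
  }
  structure(list(g_start = as.integer(g_start), g_end = as.integer(g_end)),
            class = "paired_span")
}

#' Load a nearest-neighbour parameter table
#'
#' Tables ship with the package as plain TSV under `extdata`. The default,
#' `"rna_wc_1998"`, is the INN-HB Watson-Crick RNA/RNA set at 37 degrees C
#' (16 directed dinucleotide stack terms, helix initiation, per-terminal-A-U
#' penalty, and self-complementarity symmetry term; kcal/mol).
#'
#' @param name Table name (file `nn_<name>.tsv` in the package `extdata`).
#' @return A list of class `nn_table`: `stacks` (named numeric, 16 steps),
#'   `init`, `term_au`, `symmetry`, `name`.
#' @export
nn_table <- function(name = "rna_wc_1998") {
  path <- system.file("extdata", paste0("nn_", name, ".tsv"),
                      package = "burstfit")
  if (path == "") stop("unknown nearest-neighbour table: ", name)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  vals <- stats::setNames(tab$dg37_kcal_mol, tab$step)
  steps <- as.vector(outer(names(.RNA_COMP), names(.RNA_COMP), paste0))
  missing_steps <- setdiff(steps, names(vals))
  if (length(missing_steps)) {
    stop("table ", name, " lacks steps: ", paste(missing_steps, collapse = ", "))
  }
  stacks <- vals[steps]
  if (any(stacks >= 0)) stop("all stack terms must be negative")
  if (vals[["init"]] <= 0) stop("initiation term must be positive")
  structure(list(stacks = stacks, init = vals[["init"]],
                 term_au = vals[["term_au"]], symmetry = vals[["symmetry"]],
                 name = name),
            class = "nn_table")
}

## guide position i pairs target position Lt - i + 1 (full-register
## alignment: a fully complementary target is the reverse complement of the
## guide, so its 3'-most base faces g1).
.pairs_wc <- function(g_base, t_base) {
  identical(unname(.RNA_COMP[g_base]), t_base)
}

#' Locate the contiguous paired span starting at g2
#'
#' Finds the longest run of Watson-Crick pairs beginning at guide position 2
#' against the reverse-complementary register of the target (guide position i
#' faces target position `nchar(target) - i + 1`). Wobble (G.U) pairs are not
#' counted. g1 is excluded by construction (anchored, unpaired).
#'
#' @param guide An [rna_guide()] or a character sequence.
#' @param target Target RNA sequence 5'->3' (character).
#' @return A [paired_span()] with `g_start = 2`.
#' @export
pairing_span <- function(guide, target) {
  if (!inherits(guide, "rna_guide")) guide <- rna_guide(guide)
  tg <- .check_rna(target, "target")
  g <- strsplit(guide$sequence, "")[[1]]
  tt <- strsplit(tg, "")[[1]]
  Lt <- length(tt)
  t_at <- function(i) {
    j <- Lt - i + 1L
    if (j < 1L || j > Lt) NA_character_ else tt[j]
  }
  if (is.na(t_at(2L)) || !.pairs_wc(g[2L], t_at(2L))) {
    stop("no seed-adjacent pairing: target is not complementary to the ",
         "guide at position g2")
  }
  i <- 2L
  while (i < guide$length && !is.na(t_at(i + 1L)) &&
         .pairs_wc(g[i + 1L], t_at(i + 1L))) {
    i <- i + 1L
  }
  paired_span(2L, i, guide$length)
}

#' Nearest-neighbour free energy of the paired span at 37 degrees C
#'
#' Delta-G37 = initiation + sum of dinucleotide stack terms over consecutive
#' pairs in the span + a terminal-A-U penalty at each helix end whose pair is
#' A-U, plus the symmetry term if the paired duplex is self-complementary.
#' More negative means a more stable duplex. With `include_ends = FALSE`
#' only the stack sum is returned (some analyses plot stacks only); the mode
#' is recorded on the result.
#'
#' @param guide An [rna_guide()] or character sequence.
#' @param target Target RNA 5'->3'; every span position must be
#'   Watson-Crick paired to it.
#' @param span A [paired_span()]; default [pairing_span()] of the pair.
#' @param table A [nn_table()].
#' @param include_ends Include initiation + terminal penalties (+ symmetry)
#'   in the total (default TRUE).
#' @return The free energy (kcal/mol) as a numeric scalar with attributes
#'   `components` (named vector: init, stacks, term_au, symmetry), `mode`,
#'   `table`, and `no_stacks` (TRUE for a single-pair span).
#' @export
duplex_dg37 <- function(guide, target, span = NULL,
                        table = nn_table(), include_ends = TRUE) {
  if (!inherits(guide, "rna_guide")) guide <- rna_guide(guide)
  stopifnot(inherits(table, "nn_table"))
  if (is.null(span)) span <- pairing_span(guide, target)
  stopifnot(inherits(span, "paired_span"))
  if (span$g_end > guide$length) stop("span exceeds guide length")
  tg <- .check_rna(target, "target")
  g <- strsplit(guide$sequence, "")[[1]]
  tt <- strsplit(tg, "")[[1]]
  Lt <- length(tt)
  idx <- span$g_start:span$g_end
  for (i in idx) {
    j <- Lt - i + 1L
    if (j < 1L || j > Lt || !.pairs_wc(g[i], tt[j])) {
      stop("span position g", i, " is not Watson-Crick paired to the target")
    }
  }
  top <- g[idx]
  n_pairs <- length(idx)
  stack_sum <- if (n_pairs >= 2L) {
    steps <- paste0(top[-n_pairs], top[-1L])
    sum(table$stacks[steps])
  } else 0
  term <- sum(top[c(1L, n_pairs)] %in% c("A", "U")) * table$term_au
  if (n_pairs == 1L) term <- (top[1L] %in% c("A", "U")) * table$term_au
  bottom <- rev(unname(.RNA_COMP[top]))  # paired strand 5'->3'
  sym <- if (identical(paste(top, collapse = ""),
                       paste(bottom, collapse = ""))) table$symmetry else 0
  comps <- c(init = table$init, stacks = stack_sum, term_au = term,
             symmetry = sym)
  dg <- if (include_ends) sum(comps) else stack_sum
  structure(dg,
            components = comps,
            mode = if (include_ends) "full" else "stacks_only",
            table = table$name,
            no_stacks = n_pairs < 2L)
}

#' Pairing-energy versus cleavage-rate association summary
#'
#' Orders (guide length, Delta-G37, k_burst, k_ss) entries by Delta-G37 and
#' reports Spearman rank correlations of Delta-G37 with each rate (midranks
#' for ties). A more-negative Delta-G37 (stronger pairing) accompanying a
#' larger k_burst gives Spearman(dG, k_burst) = -1 on a monotone panel.
#'
#' @param entries A data frame with columns `guide_length`, `dg37`,
#'   `k_burst`, `k_ss` (>= 3 rows).
#' @return A list of class `energy_rate_summary`: `table` (sorted by `dg37`,
#'   ascending i.e. most stable first), `spearman_k_burst`, `spearman_k_ss`.
#' @export
energy_rate_table <- function(entries) {
  req <- c("guide_length", "dg37", "k_burst", "k_ss")
  if (!is.data.frame(entries) || !all(req %in% names(entries))) {
    stop("entries must be a data frame with columns ",
         paste(req, collapse = ", "))
  }
  if (nrow(entries) < 3L) stop("need >= 3 entries for an association summary")
  ord <- order(entries$dg37)
  tab <- entries[ord, req]
  rownames(tab) <- NULL
  structure(list(
    table = tab,
    spearman_k_burst = stats::cor(entries$dg37, entries$k_burst,
                                  method = "spearman"),
    spearman_k_ss = stats::cor(entries$dg37, entries$k_ss,
                               method = "spearman")),
    class = "energy_rate_summary")
}

#' @export
print.energy_rate_summary <- function(x, ...) {
  cat("pairing energy vs cleavage rates (sorted by dG37):\n")
  print(x$table)
  cat(sprintf("Spearman(dG37, k_burst) = %+.3f;  Spearman(dG37, k_ss) = %+.3f\n",
              x$spearman_k_burst, x$spearman_k_ss))
  invisible(x)
}
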