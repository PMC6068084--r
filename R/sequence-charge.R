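AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' An amino-acid chain with plain sequential numbering
#'
#' Positions are 1-based sequential indices into the chain; no Kabat/IMGT
#' renumbering is applied, so mutation labels like "S63R" refer to the
#' 63rd residue of the supplied sequence.
#'
#' @param identifier Chain label.
#' @param residues One-letter amino-acid string (20-letter alphabet).
#' @return An object of class `chain_seq`.
#' @export
chain_seq <- function(identifier, residues) {
  residues <- toupper(gsub("[[:space:]]", "", residues))
  letters <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(letters), AA_ALPHABET)
  if (length(bad) > 0)
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  structure(list(identifier = identifier, residues = residues),
            class = "chain_seq")
}

#' @export
print.chain_seq <- function(x, ...) {
  cat(sprintf(">%s (%d aa)\n%s\n", x$identifier, nchar(x$residues),
              x$residues))
  invisible(x)
}

#' Parse mutation labels such as "S63R" or "LS63R"
#'
#' The one-letter prefix before the original residue, when present, is a
#' chain tag ("L" for light chain) and is discarded; "LS63R" and "S63R"
#' both mean Ser63 -> Arg.
#'
#' @param specs Character vector of mutation labels, or a single
#'   comma-separated string.
#' @return A data.frame with columns `position`, `original`, `replacement`.
#' @export
#' @examples
#' parse_mutations("LS63R, LS65R, LS67R")
parse_mutations <- function(specs) {
  if (length(specs) == 1L && grepl(",", specs))
    specs <- strsplit(specs, ",")[[1]]
  specs <- trimws(specs)
  specs <- specs[nzchar(specs)]
  m <- regmatches(specs, regexec("^([HL]?)([A-Z])([0-9]+)([A-Z])$", specs))
  bad <- specs[vapply(m, length, 1L) == 0L]
  if (length(bad) > 0)
    stop("cannot parse mutation label(s): ", paste(bad, collapse = ", "))
  out <- data.frame(
    position = as.integer(vapply(m, `[`, "", 4L)),
    original = vapply(m, `[`, "", 3L),
    replacement = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE)
  if (any(out$original == out$replacement))
    stop("original and replacement residues must differ")
  out
}

#' Apply point mutations to a chain
#'
#' Each mutation's stated original residue is checked against the sequence
#' before substitution; a mismatch is an error that names the offending
#' position, as are duplicate positions. Only the specified positions
#' change and the chain length is preserved.
#'
#' @param seq A [chain_seq].
#' @param specs A data.frame from [parse_mutations] (columns `position`,
#'   `original`, `replacement`), or a character vector of labels.
#' @param identifier Label for the mutated chain.
#' @return The mutated [chain_seq].
#' @export
#' @examples
#' wt <- chain_seq("VL", "ASRSTSVSKL")
#' apply_mutations(wt, "S2R")
apply_mutations <- function(seq, specs,
                            identifier = paste0(seq$identifier, "_mut")) {
  stopifnot(inherits(seq, "chain_seq"))
  if (is.character(specs)) specs <- parse_mutations(specs)
  if (nrow(specs) == 0) return(chain_seq(seq$identifier, seq$residues))
  if (anyDuplicated(specs$position))
    stop("duplicate mutation position(s): ",
         paste(unique(specs$position[duplicated(specs$position)]),
               collapse = ", "))
  letters <- strsplit(seq$residues, "")[[1]]
  if (any(specs$position < 1 | specs$position > length(letters)))
    stop("mutation position outside the sequence (length ",
         length(letters), ")")
  found <- letters[specs$position]
  bad <- which(found != specs$original)
  if (length(bad) > 0)
    stop("original residue mismatch at position ",
         paste0(specs$position[bad], " (expected ", specs$original[bad],
                ", found ", found[bad], ")", collapse = "; "))
  letters[specs$position] <- specs$replacement
  chain_seq(identifier, paste(letters, collapse = ""))
}

#' pKa tables for ionizable groups
#'
#' Named vector of side-chain and terminal pKa values. `Nterm` and `Cterm`
#' are the alpha-amino and alpha-carboxyl groups. The default is the EMBOSS
#' set; "lehninger" is provided as an alternative to check robustness of
#' charge orderings to the pKa source.
#'
#' @param name One of "emboss", "lehninger".
#' @return Named numeric vector with entries C, D, E, H, K, R, Y, Nterm,
#'   Cterm.
#' @export
pka_table <- function(name = c("emboss", "lehninger")) {
  name <- match.arg(name)
  switch(name,
    emboss = c(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5,
               Y = 10.1, Nterm = 8.6, Cterm = 3.6),
    lehninger = c(C = 8.3, D = 3.65, E = 4.25, H = 6.0, K = 10.53,
                  R = 12.48, Y = 10.07, Nterm = 9.69, Cterm = 2.34))
}

BASIC_GROUPS  <- c("H", "K", "R", "Nterm")
ACIDIC_GROUPS <- c("C", "D", "E", "Y", "Cterm")

#' Net charge of a chain by the Henderson-Hasselbalch approximation
#'
#' Sums the average protonation charge of every ionizable group at the
#' given pH: +1 / (1 + 10^(pH - pKa)) for basic groups and
#' -1 / (1 + 10^(pKa - pH)) for acidic groups. All groups are treated as
#' independent with model-compound pKa values; no structural or disulfide
#' corrections are applied.
#'
#' @param seq A [chain_seq], or a list of them (charges are summed over
#'   chains, e.g. for a two-chain hormone).
#' @param pH pH value in (0, 14); vectorised.
#' @param pka Named pKa vector, see [pka_table].
#' @param include_termini Count the alpha-amino and alpha-carboxyl termini
#'   (per chain)?
#' @return Net charge in elementary units.
#' @export
#' @examples
#' net_charge(chain_seq("x", "GGDGG"), pH = 3.9, include_termini = FALSE)
net_charge <- function(seq, pH = 7.4, pka = pka_table("emboss"),
                       include_termini = TRUE) {
  if (inherits(seq, "chain_seq")) seq <- list(seq)
  stopifnot(all(vapply(seq, inherits, TRUE, "chain_seq")))
  if (any(pH <= 0 | pH >= 14)) stop("'pH' must lie in (0, 14)")
  need <- c("C", "D", "E", "H", "K", "R", "Y")
  if (!all(need %in% names(pka)))
    stop("pKa table must cover ", paste(need, collapse = ", "))
  if (include_termini && !all(c("Nterm", "Cterm") %in% names(pka)))
    stop("pKa table must cover Nterm and Cterm when termini are included")
  counts <- table(factor(unlist(lapply(seq, function(s)
    strsplit(s$residues, "")[[1]])), levels = AA_ALPHABET))
  n_chains <- length(seq)
  vapply(pH, function(p) {
    pos <- sum(vapply(intersect(BASIC_GROUPS, names(counts)), function(g)
      counts[[g]] / (1 + 10^(p - pka[[g]])), numeric(1)))
    neg <- sum(vapply(intersect(ACIDIC_GROUPS, names(counts)), function(g)
      counts[[g]] / (1 + 10^(pka[[g]] - p)), numeric(1)))
    if (include_termini) {
      pos <- pos + n_chains / (1 + 10^(p - pka[["Nterm"]]))
      neg <- neg + n_chains / (1 + 10^(pka[["Cterm"]] - p))
    }
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection on the charge curve
#'
#' The net-charge curve is continuous and strictly decreasing in pH, so
#' when the chain carries at least one basic and one acidic group its zero
#' is unique; it is located by bisection on [0.1, 13.9] to |charge| < 1e-6.
#'
#' @inheritParams net_charge
#' @return The pI (pH units).
#' @export
isoelectric_point <- function(seq, pka = pka_table("emboss"),
                              include_termini = TRUE) {
  f <- function(p) net_charge(seq, p, pka, include_termini)
  lo <- 0.1; hi <- 13.9
  f_lo <- f(lo); f_hi <- f(hi)
  if (!(f_lo > 0 && f_hi < 0))
    stop("pI undefined: charge curve does not change sign ",
         "(need at least one basic and one acidic group)")
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  pI <- (lo + hi) / 2
  stopifnot(abs(f(pI)) < 1e-6)
  pI
}

#' Read protein chains from a FASTA file
#'
#' @param path Path to a (plain-text) FASTA file of amino-acid sequences.
#' @return A list of [chain_seq] objects, one per record.
#' @export
read_chain_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    return(lapply(seq_along(aa), function(i)
      chain_seq(names(aa)[i], as.character(aa[[i]]))))
  }
  lines <- readLines(path)
  idx <- grep("^>", lines)
  if (length(idx) == 0) stop("no FASTA records in ", path)
  ends <- c(idx[-1] - 1L, length(lines))
  lapply(seq_along(idx), function(i) {
    id <- sub("^>\\s*", "", lines[idx[i]])
    id <- sub("\\s.*$", "", id)
    body <- lines[setdiff(seq(idx[i] + 1L, ends[i]), idx)]
    chain_seq(id, paste(body, collapse = ""))
  })
}

#' Synthetic wild-type VL domain used throughout the examples
#'
#' A synthetic 107-residue kappa-type light-chain variable domain carrying
#' serines at sequential positions 63, 65, 67, 70 and 72 — the framework-3
#' positions targeted by the charge-mutant panel. It is a constructed
#' stand-in (the real antibody's VL sequence is not publicly machine-
#' readable), adequate for charge bookkeeping but not a real antibody
#' sequence.
#'
#' @return A [chain_seq] named "VL_wt_synthetic".
#' @export
vl_wildtype <- function() {
  chain_seq("VL_wt_synthetic", paste0(
    "DIVMTQSPSSLAVSAGEKVTMSCKSSQSLLNSRTRKNYLAWYQQKPGQSPKLLIYWASTR",
    "EGSVSDSFTSGSGTD",
    "FTLTISSVQAEDLAVYYCKQSYNLYTFGGGTK"))
}

#' The charge-mutant panel of the framework-3 study
#'
#' Mutation labels for the five FR3 charge mutants: R3 (three Ser -> Arg),
#' and the five-position R5, K5, D5, E5 panels at positions 63, 65, 67,
#' 70, 72 of the light chain.
#'
#' @return Named list of character vectors of mutation labels.
#' @export
mutant_panel <- function() {
  pos5 <- c(63, 65, 67, 70, 72)
  list(
    R3 = paste0("LS", c(63, 65, 67), "R"),
    R5 = paste0("LS", pos5, "R"),
    K5 = paste0("LS", pos5, "K"),
    D5 = paste0("LS", pos5, "D"),
    E5 = paste0("LS", pos5, "E"))
}

#' Mature human insulin as two chains
#'
#' The 21-residue A chain and 30-residue B chain of the mature hormone
#' (the processed two-chain form, not the single-chain precursor). Used
#' for the net-charge consistency check at physiological pH.
#'
#' @return A list of two [chain_seq] objects.
#' @export
human_insulin <- function() {
  list(
    chain_seq("insulin_A", "GIVEQCCTSICSLYQLENYCN"),
    chain_seq("insulin_B", "FVNQHLCGSHLVEALYLVCGERGFFYTPKT"))
}
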