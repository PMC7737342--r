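PNP_TIERS <- c("eumetazoan", "bilaterian", "protostome", "lophotrochozoan",
               "annelid", "species_specific")

#' Read a family catalog from structured text
#'
#' The catalog maps neuropeptide families to phylogenetic-distribution tiers
#' and carries reference peptides and/or a C-terminal motif per family. The
#' format is stanza-based plain text: stanzas separated by blank lines,
#' fields `family:`, `tier:`, `motif:` (optional, `x` wildcards allowed) and
#' `peptides:` (optional, whitespace-separated amino-acid strings). Lines
#' starting with `#` are comments.
#'
#' @param path Path to a catalog file.
#' @return An object of class `family_catalog`: a list of entries, each with
#'   `family`, `tier`, `motif`, `peptides`.
#' @export
read_family_catalog <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  entries <- list()
  for (b in blocks) {
    b <- b[nzchar(trimws(b))]
    if (!length(b)) next
    kv <- regmatches(b, regexec("^\\s*(\\w+):\\s*(.*)$", b))
    fields <- setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
    if (!"family" %in% names(fields) || !"tier" %in% names(fields)) {
      stop("catalog stanza missing family/tier field")
    }
    tier <- trimws(fields[["tier"]])
    if (!tier %in% PNP_TIERS) {
      stop("unknown tier '", tier, "' for family ", fields[["family"]])
    }
    peptides <- if ("peptides" %in% names(fields)) {
      strsplit(trimws(fields[["peptides"]]), "\\s+")[[1L]]
    } else character()
    motif <- if ("motif" %in% names(fields)) trimws(fields[["motif"]]) else ""
    if (!length(peptides) && !nzchar(motif)) {
      stop("catalog entry ", fields[["family"]],
           " needs at least one reference peptide or a motif")
    }
    entries[[length(entries) + 1L]] <- list(
      family = trimws(fields[["family"]]), tier = tier,
      motif = motif, peptides = toupper(peptides))
  }
  fams <- vapply(entries, `[[`, "", "family")
  if (anyDuplicated(fams)) {
    stop("duplicate family in catalog: ", fams[duplicated(fams)][1L])
  }
  structure(entries, class = "family_catalog")
}

#' Write a family catalog
#' @param catalog A `family_catalog`.
#' @param path Output path.
#' @export
write_family_catalog <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in catalog) {
    writeLines(c(paste0("family: ", e$family), paste0("tier: ", e$tier)), con)
    if (nzchar(e$motif)) writeLines(paste0("motif: ", e$motif), con)
    if (length(e$peptides)) {
      writeLines(paste0("peptides: ", paste(e$peptides, collapse = " ")), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' @export
print.family_catalog <- function(x, ...) {
  cat(sprintf("<family_catalog> %d families\n", length(x)))
  tiers <- vapply(x, `[[`, "", "tier")
  print(table(factor(tiers, levels = PNP_TIERS)))
  invisible(x)
}

#' Assign a precursor to a neuropeptide family and phylogenetic tier
#'
#' The best family is the catalog entry maximising the length-normalised
#' local-alignment identity between any of the precursor's mature peptides
#' and any reference peptide: identical aligned positions divided by the
#' length of the longer of the two peptides, so short spurious local
#' alignments cannot reach high identity. The family is assigned when that
#' identity reaches `min_identity`, or when the precursor's discovered
#' C-terminal motif equals the entry's motif (motif match overrides
#' identity). Otherwise the precursor is `novel` / `species_specific`. Ties
#' are broken by catalog order.
#'
#' @param a A `pnp_annotation` with at least one mature peptide.
#' @param catalog A `family_catalog` (may be empty).
#' @param min_identity Identity threshold in `[0, 1]` (default 0.5).
#' @param config [pnp_config()] list supplying gap penalties.
#' @return The annotation with `family` and `tier` filled.
#' @export
assign_family_and_tier <- function(a, catalog, min_identity = 0.5,
                                   config = pnp_config()) {
  stopifnot(inherits(a, "pnp_annotation"))
  a$family <- "novel"
  a$tier <- "species_specific"
  if (!length(catalog) || !nrow(a$peptides)) return(a)
  peps <- a$peptides$processed_seq
  best_ident <- -1
  best_entry <- NULL
  motif_entry <- NULL
  for (e in catalog) {
    if (is.null(motif_entry) && nzchar(e$motif) && nzchar(a$motif) &&
        identical(e$motif, a$motif)) {
      motif_entry <- e
    }
    if (length(e$peptides)) {
      ident <- max(vapply(e$peptides, function(ref)
        max(vapply(peps, function(p) {
          al <- local_align(p, ref, gap_open = config$gap_open,
                            gap_extend = config$gap_extend)
          if (is.na(al$identity)) return(0)
          n_identical <- al$identity * nchar(al$a_aln)
          n_identical / max(nchar(p), nchar(ref))
        }, numeric(1L))), numeric(1L)))
      if (ident > best_ident + 1e-12) {
        best_ident <- ident
        best_entry <- e
      }
    }
  }
  if (!is.null(motif_entry)) {
    a$family <- motif_entry$family
    a$tier <- motif_entry$tier
  } else if (!is.null(best_entry) && best_ident >= min_identity) {
    a$family <- best_entry$family
    a$tier <- best_entry$tier
  }
  a
}

#' Tally precursor counts per phylogenetic tier
#'
#' @param annotations List of classified `pnp_annotation` objects.
#' @return Named integer vector over the six tiers; sums to the input size.
#' @export
tally_tiers <- function(annotations) {
  tiers <- vapply(annotations, `[[`, "", "tier")
  if (length(tiers) && any(!nzchar(tiers))) {
    stop("unclassified annotation (empty tier); run assign_family_and_tier")
  }
  tab <- table(factor(tiers, levels = PNP_TIERS))
  setNames(as.integer(tab), PNP_TIERS)
}
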