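#' UMI-based duplicate collapsing
#'
#' During library preparation a random molecular barcode (UMI) is attached
#' to each original cfDNA molecule, so PCR and optical duplicates can be
#' recognised and collapsed before allele counting. Collapsing corrects
#' the bias PCR duplicates introduce into allele-frequency estimates and
#' suppresses isolated sequencing errors through a per-family consensus.
#'
#' Reads are grouped into families by the exact tuple
#' `(umi, chrom, start, strand)`; no error-tolerant UMI merging is
#' attempted. Each family contributes one consensus observation: the
#' strict-majority allele of its member reads. Families with no strict
#' majority (ties) are discarded from both the depth and the variant count.
#'
#' @name dedup
NULL

#' Read tagged read records from a TSV
#'
#' Columns: `umi, chrom, start, strand, allele`.
#'
#' @param path Path to the TSV.
#' @return Tibble of tagged reads.
#' @export
read_tagged_reads <- function(path) {
  reads <- readr::read_tsv(path, col_types = readr::cols(
    umi = "c", chrom = "c", start = "i", strand = "c", allele = "c"
  ), progress = FALSE)
  validate_reads(reads)
}

validate_reads <- function(reads) {
  req <- c("umi", "chrom", "start", "strand", "allele")
  miss <- setdiff(req, names(reads))
  if (length(miss) > 0)
    stop("tagged-read table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!nzchar(reads$umi))) stop("empty UMI barcode", call. = FALSE)
  if (any(reads$start < 1)) stop("read start must be >= 1", call. = FALSE)
  if (any(!reads$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  reads
}

#' Group tagged reads into UMI families
#'
#' All reads must interrogate the same locus. The family key is
#' `(umi, chrom, start, strand)`; the returned tibble carries a
#' `family` column and families partition the input.
#'
#' @param reads Tagged-read tibble (see [read_tagged_reads()]).
#' @return The reads with a `family` key column.
#' @export
group_reads <- function(reads) {
  reads <- validate_reads(reads)
  if (nrow(reads) == 0) { reads$family <- character(0); return(reads) }
  if (n_distinct(reads$chrom) > 1)
    stop("reads span more than one locus; group one locus at a time",
         call. = FALSE)
  reads$family <- paste(reads$umi, reads$chrom, reads$start, reads$strand,
                        sep = "|")
  reads
}

#' Collapse UMI families into deduplicated allele counts
#'
#' Each family votes once with its strict-majority consensus allele;
#' tied families are dropped from both counts. `depth` is the number of
#' surviving families and `alt_families` the number whose consensus equals
#' the queried alternate allele.
#'
#' @param grouped Output of [group_reads()].
#' @param alt_allele The alternate allele being interrogated at the locus.
#' @return List with `depth`, `alt_families`, `vaf` (NA when depth is 0)
#'   and the per-family `consensus` tibble.
#' @export
collapse_families <- function(grouped, alt_allele) {
  if (nrow(grouped) == 0)
    return(list(depth = 0L, alt_families = 0L, vaf = NA_real_,
                consensus = tibble(family = character(0),
                                   allele = character(0))))
  if (!"family" %in% names(grouped))
    stop("input must come from group_reads()", call. = FALSE)
  cons <- grouped %>%
    group_by(.data$family) %>%
    summarise(allele = strict_majority(.data$allele), .groups = "drop") %>%
    filter(!is.na(.data$allele))
  depth <- nrow(cons)
  alt_fam <- sum(cons$allele == alt_allele)
  list(depth = as.integer(depth), alt_families = as.integer(alt_fam),
       vaf = if (depth > 0) alt_fam / depth else NA_real_,
       consensus = cons)
}

# strict majority of a character vector; NA on ties
strict_majority <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return(NA_character_)
  names(tab)[1]
}

#' Deduplicated counts for one locus in one read set
#'
#' Convenience wrapper: [group_reads()] then [collapse_families()].
#'
#' @param reads Tagged-read tibble for one locus.
#' @param alt_allele Alternate allele at the locus.
#' @return List as in [collapse_families()].
#' @export
dedup_counts <- function(reads, alt_allele) {
  collapse_families(group_reads(reads), alt_allele)
}
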