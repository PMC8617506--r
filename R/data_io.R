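#' Default annotation vocabulary
#'
#' Functional group labels recognised by [read_annotation()]. Labels outside
#' this vocabulary are retained but remapped to `"other"` (with a warning) so
#' that the enrichment universe never shrinks silently.
#'
#' @format Character vector of group labels.
#' @export
annotation_vocabulary <- c(
  "PhANG", "PhAPG", "plastid_ribosome_NE", "plastid_ribosome_PE",
  "cytosolic_ribosome", "TPR", "carbon_fixation", "coupled", "uncoupled",
  "other"
)

#' Validate an abundance matrix
#'
#' An abundance matrix is a numeric matrix of nonnegative quantities
#' (reporter intensities or read counts) with unique feature row names and
#' unique sample column names. Missing quantifications are `NA`, never 0.
#'
#' @param x numeric matrix with rownames (features) and colnames (samples).
#' @return `x`, invisibly, after validation.
#' @export
validate_abundance <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("abundance must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("abundance matrix requires feature rownames and sample colnames")
  dup_f <- rownames(x)[duplicated(rownames(x))]
  if (length(dup_f))
    stop("duplicate feature id(s): ", paste(unique(dup_f), collapse = ", "))
  dup_s <- colnames(x)[duplicated(colnames(x))]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  neg <- which(x < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative value at feature '%s', sample '%s'",
                 rownames(x)[neg[1, 1]], colnames(x)[neg[1, 2]]))
  invisible(x)
}

#' Read an abundance table
#'
#' Reads a TSV whose first column holds feature ids and whose remaining
#' columns hold one sample each. Empty cells and `"NA"` become missing
#' values (`NA`), which are distinct from zero.
#'
#' @param path path to a tab-separated file with a header row.
#' @return numeric matrix (features x samples); see [validate_abundance()].
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("abundance table needs a feature column plus >=1 sample")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_abundance(m)
  m
}

#' Write an abundance table
#'
#' Inverse of [read_abundance_table()]: TSV, UTF-8, header row, missing
#' values rendered `"NA"`. Round-trips losslessly.
#'
#' @param x abundance matrix.
#' @param path output path.
#' @param feature_col name for the feature-id column (default `"feature_id"`).
#' @export
write_abundance_table <- function(x, path, feature_col = "feature_id") {
  validate_abundance(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  write_tsv(df, path)
}

#' Write a result table as TSV
#'
#' All package writers funnel through this: tab-separated, UTF-8, header
#' row, `NA` for missing, no quoting, no row names.
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         " in ", path)
  df
}

#' Read a sample design table
#'
#' Required columns: `sample_id`, `genotype`, `replicate`, `run`, `tissue`,
#' `role` (one of inbred / hybrid / mutant). Genotype labels are
#' case-sensitive opaque strings; reciprocal crosses are distinct genotypes.
#'
#' @param path TSV path.
#' @return validated design data frame.
#' @export
read_design <- function(path) {
  df <- read_tsv_checked(path,
    c("sample_id", "genotype", "replicate", "run", "tissue", "role"))
  validate_design(df)
  df
}

#' @rdname read_design
#' @param design design data frame to validate.
#' @export
validate_design <- function(design) {
  dup <- design$sample_id[duplicated(design$sample_id)]
  if (length(dup))
    stop("duplicate sample id(s) in design: ", paste(unique(dup), collapse = ", "))
  if (any(!design$role %in% c("inbred", "hybrid", "mutant")))
    stop("role must be one of inbred, hybrid, mutant")
  if (any(is.na(design$replicate)) || any(design$replicate < 1))
    stop("replicate must be a positive integer")
  invisible(design)
}

#' Read a cross panel table
#'
#' Required columns: `hybrid`, `parent_female`, `parent_male`. Parents of a
#' cross must be distinct; hybrid labels must be unique (reciprocal crosses
#' are separate rows). When `design` is supplied, every parent must occur in
#' the design.
#'
#' @param path TSV path.
#' @param design optional design data frame for cross-reference checks.
#' @return validated cross-panel data frame.
#' @export
read_cross <- function(path, design = NULL) {
  df <- read_tsv_checked(path, c("hybrid", "parent_female", "parent_male"))
  validate_cross(df, design)
  df
}

#' @rdname read_cross
#' @param cross cross-panel data frame to validate.
#' @export
validate_cross <- function(cross, design = NULL) {
  same <- cross$hybrid[cross$parent_female == cross$parent_male]
  if (length(same))
    stop("cross with identical parents: ", paste(same, collapse = ", "))
  dup <- cross$hybrid[duplicated(cross$hybrid)]
  if (length(dup))
    stop("duplicate hybrid label(s): ", paste(unique(dup), collapse = ", "))
  if (!is.null(design)) {
    known <- unique(design$genotype)
    absent <- setdiff(unique(c(cross$parent_female, cross$parent_male)), known)
    if (length(absent))
      stop("parent genotype(s) absent from design: ",
           paste(absent, collapse = ", "))
  }
  invisible(cross)
}

#' Read a trait table
#'
#' Required columns: `genotype`, `height_cm` (strictly positive). One row
#' per genotype.
#'
#' @param path TSV path.
#' @return validated trait data frame.
#' @export
read_trait <- function(path) {
  df <- read_tsv_checked(path, c("genotype", "height_cm"))
  validate_trait(df)
  df
}

#' @rdname read_trait
#' @param traits trait data frame to validate.
#' @export
validate_trait <- function(traits) {
  dup <- traits$genotype[duplicated(traits$genotype)]
  if (length(dup))
    stop("duplicate genotype(s) in trait table: ",
         paste(unique(dup), collapse = ", "))
  bad <- traits$genotype[is.na(traits$height_cm) | traits$height_cm <= 0]
  if (length(bad))
    stop("nonpositive or missing height for genotype(s): ",
         paste(bad, collapse = ", "))
  invisible(traits)
}

#' Read a feature annotation table
#'
#' Required columns: `feature_id`, `groups` (semicolon-separated group
#' labels; may be empty). Labels not in `vocabulary` are remapped to
#' `"other"` with a warning rather than dropped, so the enrichment universe
#' is preserved. Pass `vocabulary = NULL` to accept any label.
#'
#' @param path TSV path.
#' @param vocabulary allowed labels, or `NULL` for no restriction.
#' @return data frame with columns `feature_id`, `groups`.
#' @export
read_annotation <- function(path, vocabulary = annotation_vocabulary) {
  df <- read_tsv_checked(path, c("feature_id", "groups"))
  df$groups[is.na(df$groups)] <- ""
  if (!is.null(vocabulary)) {
    sets <- strsplit(df$groups, ";", fixed = TRUE)
    unknown <- setdiff(unique(unlist(sets)), c(vocabulary, ""))
    if (length(unknown)) {
      warning("unknown annotation label(s) remapped to 'other': ",
              paste(unknown, collapse = ", "))
      sets <- lapply(sets, function(g) {
        g[g %in% unknown] <- "other"
        unique(g)
      })
      df$groups <- vapply(sets, paste, "", collapse = ";")
    }
  }
  dup <- df$feature_id[duplicated(df$feature_id)]
  if (length(dup))
    stop("duplicate feature id(s) in annotation: ",
         paste(unique(dup), collapse = ", "))
  df
}

#' Expand an annotation table to group membership lists
#'
#' @param annotation data frame as returned by [read_annotation()].
#' @return named list mapping each group label to its feature ids.
#' @export
annotation_sets <- function(annotation) {
  sets <- strsplit(annotation$groups, ";", fixed = TRUE)
  ids <- rep(annotation$feature_id, lengths(sets))
  labs <- unlist(sets)
  keep <- !is.na(labs) & labs != ""
  split(ids[keep], labs[keep])
}
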