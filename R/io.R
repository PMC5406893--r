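# Readers and writers for the tab-separated interchange formats: expression
# matrices (gene-id first column, sample header), sample annotations,
# signature gene lists, activity/phenotype tables in the supplementary
# layout, and dose-response panels.

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Duplicate gene ids are collapsed by their mean (with a warning);
#' duplicate sample ids are an error, as is any non-numeric cell (reported
#' with its coordinates).
#'
#' @param path Path to a tab-separated text file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("'", path, "' has no data rows or no sample columns",
         call. = FALSE)
  }
  genes <- as.character(df[[1]])
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "NA")
      if (length(bad)) {
        stop("non-numeric value at row ", bad[1], ", column '",
             samples[j], "'", call. = FALSE)
      }
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    warning("duplicate gene id(s) collapsed by mean", call. = FALSE)
    m <- do.call(rbind, lapply(split(seq_along(genes), genes), function(i) {
      colMeans(m[i, , drop = FALSE])
    }))
    m <- m[unique(genes), , drop = FALSE]
  }
  m
}

#' Write a gene x sample expression matrix to TSV
#'
#' @param expr Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_column Name of the gene-id column (default "gene").
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, id_column = "gene") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a signature gene list as two-column TSV (gene, signed weight)
#' @param sig A `gfrn_signature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  w <- ifelse(sig$genes$direction == "up", 1, -1) * abs(sig$genes$weight)
  utils::write.table(
    data.frame(gene = sig$genes$gene, weight = w),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature gene list written by [write_signature()]
#'
#' Directions are recovered from the sign of the weight.
#'
#' @param path Signature TSV path.
#' @param anchor Anchor gene (default: the largest-|weight| gene).
#' @param pathway Optional pathway name.
#' @return A `gfrn_signature` (without training baseline).
#' @export
read_signature <- function(path, anchor = NULL, pathway = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "weight") %in% names(df)))
  if (is.null(anchor)) anchor <- df$gene[which.max(abs(df$weight))]
  eff <- stats::setNames(df$weight, df$gene)
  genes <- data.frame(
    gene = df$gene,
    direction = ifelse(df$weight >= 0, "up", "down"),
    weight = df$weight, stringsAsFactors = FALSE)
  structure(
    list(pathway = pathway, genes = genes, anchor = anchor,
         K = nrow(genes), effects = eff, control_baseline = NULL),
    class = "gfrn_signature")
}

#' Write phenotype calls (with activities) as TSV
#' @param calls A `gfrn_phenotypes` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a scaled-activity / phenotype table in the supplementary layout
#'
#' The layout is one row per sample: a sample-id column, one column per
#' pathway with z-scaled activity, and phenotype and cluster columns.
#' Column names can be remapped via `column_map`; phenotype synonyms (e.g.
#' capitalized labels) can be translated via `synonyms`. A missing pathway
#' column is an error naming that pathway.
#'
#' @param path TSV path.
#' @param pathways Expected pathway columns (default all seven).
#' @param column_map Optional named character vector mapping expected
#'   column names (sample, phenotype, cluster, pathway names) to the names
#'   actually used in the file.
#' @param synonyms Optional named character vector mapping file phenotype
#'   values to "survival"/"growth".
#' @return List with `scaled` (pathway x sample matrix) and `calls`
#'   (data.frame: sample, phenotype, cluster).
#' @export
read_supplementary_activity <- function(path, pathways = gfrn_pathways(),
                                        column_map = NULL,
                                        synonyms = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cname <- function(nm) {
    if (!is.null(column_map) && nm %in% names(column_map)) column_map[[nm]]
    else nm
  }
  for (p in pathways) {
    if (!cname(p) %in% names(df)) {
      stop("missing pathway column: ", p, call. = FALSE)
    }
  }
  sample_col <- cname("sample")
  if (!sample_col %in% names(df)) sample_col <- names(df)[1]
  samples <- as.character(df[[sample_col]])
  scaled <- t(as.matrix(df[, vapply(pathways, cname, character(1)),
                           drop = FALSE]))
  dimnames(scaled) <- list(pathways, samples)
  pheno <- if (cname("phenotype") %in% names(df)) {
    v <- as.character(df[[cname("phenotype")]])
    if (!is.null(synonyms)) {
      mapped <- !is.na(match(v, names(synonyms)))
      v[mapped] <- synonyms[v[mapped]]
    }
    bad <- setdiff(unique(v), c("survival", "growth"))
    if (length(bad)) {
      stop("unrecognized phenotype value(s): ",
           paste(bad, collapse = ", "),
           "; supply a synonyms mapping", call. = FALSE)
    }
    v
  } else {
    NA_character_
  }
  cluster <- if (cname("cluster") %in% names(df)) df[[cname("cluster")]]
             else NA_integer_
  list(scaled = scaled,
       calls = data.frame(sample = samples, phenotype = pheno,
                          cluster = cluster, stringsAsFactors = FALSE))
}

#' Write a scaled-activity / phenotype table in the supplementary layout
#'
#' @param scaled Pathway x sample z-scaled activity matrix.
#' @param calls Optional `gfrn_phenotypes` with phenotype (and cluster).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_supplementary_activity <- function(scaled, calls = NULL, path) {
  df <- data.frame(sample = colnames(scaled), t(scaled),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(calls)) {
    idx <- match(df$sample, calls$sample)
    df$phenotype <- calls$phenotype[idx]
    if (!is.null(calls$cluster)) df$cluster <- calls$cluster[idx]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
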