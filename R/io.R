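#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

#' Construct an expression study
#'
#' An expression study is one cohort's log2-scale gene-by-sample matrix plus a
#' case/control label per sample. Values are assumed already background
#' corrected, normalized and log2 transformed; the package performs no
#' probe-level preprocessing.
#'
#' @param study_id Study label.
#' @param values Numeric matrix, genes in rows (rownames are gene or probe
#'   identifiers), samples in columns (colnames are sample identifiers).
#' @param group Character or factor of `"case"` / `"control"`, one per column
#'   of `values`, in column order.
#' @return An object of class `"expression_study"`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expression_study("bronchial", m, c("case", "case", "control", "control"))
#' @export
expression_study <- function(study_id, values, group) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  group <- as.character(group)
  if (length(group) != ncol(values)) {
    stop("`group` must have one label per sample column", call. = FALSE)
  }
  bad <- setdiff(unique(group), c("case", "control"))
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected \"case\" or \"control\")", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing", call. = FALSE)
  }
  structure(
    list(study_id = as.character(study_id), values = values,
         group = stats::setNames(group, colnames(values))),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study \"%s\": %d genes x %d samples (%d case / %d control)>\n",
              x$study_id, nrow(x$values), ncol(x$values),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

#' @describeIn expression_study Long tibble (gene, sample, group, value).
#' @param x An `expression_study`.
#' @param ... Unused.
#' @export
tidy.expression_study <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value") |>
    dplyr::mutate(study_id = x$study_id,
                  group = unname(x$group[.data$sample]),
                  .after = "gene")
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read expression studies from delimited text
#'
#' The expression file is tab separated with a header; the first column holds
#' gene (or probe) identifiers and the remaining columns one sample each. The
#' annotation file maps every sample to a `study_id` and a `group` of `"case"`
#' or `"control"`. One [expression_study()] is returned per `study_id`, with
#' sample order as in the matrix file.
#'
#' @param path Expression matrix TSV.
#' @param annotation_path Sample annotation TSV with columns `sample`,
#'   `study_id`, `group`.
#' @return Named list of `expression_study` objects, one per study.
#' @export
read_expression <- function(path, annotation_path) {
  raw <- read_tsv_quiet(path, col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 2L) stop("expression file needs a gene column plus >=1 sample column", call. = FALSE)
  gene_col <- names(raw)[1]
  samples <- names(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals), dimnames = NULL))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric expression value \"%s\" at gene \"%s\", sample \"%s\"",
                 vals[bad[1, 1], bad[1, 2]], raw[[gene_col]][bad[1, 1]],
                 samples[bad[1, 2]]), call. = FALSE)
  }
  if (anyNA(num)) stop("missing expression values are not allowed", call. = FALSE)
  dimnames(num) <- list(raw[[gene_col]], samples)

  ann <- read_tsv_quiet(annotation_path)
  need <- c("sample", "study_id", "group")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols) > 0) {
    stop("annotation file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(samples, ann$sample)
  if (length(unknown) > 0) {
    stop("sample(s) in expression matrix absent from annotation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ann <- ann[match(samples, ann$sample), ]
  studies <- lapply(split(seq_along(samples), ann$study_id), function(idx) {
    expression_study(ann$study_id[idx[1]],
                     num[, idx, drop = FALSE],
                     ann$group[idx])
  })
  studies[unique(ann$study_id)]
}

#' Write expression studies to delimited text
#'
#' Inverse of [read_expression()]: all studies are written side by side into a
#' single matrix TSV (genes must agree across studies) plus an annotation TSV.
#'
#' @param studies List of [expression_study()] objects.
#' @param path,annotation_path Output TSV paths.
#' @return `path`, invisibly.
#' @export
write_expression <- function(studies, path, annotation_path) {
  stopifnot(length(studies) >= 1)
  genes <- rownames(studies[[1]]$values)
  for (s in studies) stopifnot(identical(rownames(s$values), genes))
  mat <- do.call(cbind, lapply(studies, function(s) s$values))
  tibble::as_tibble(mat, rownames = "gene") |>
    readr::write_tsv(path, progress = FALSE)
  ann <- purrr::map_dfr(studies, function(s) {
    tibble::tibble(sample = colnames(s$values), study_id = s$study_id,
                   group = unname(s$group))
  })
  readr::write_tsv(ann, annotation_path, progress = FALSE)
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' GMT is tab separated, one set per line: set name, description, then member
#' genes. Duplicate genes within a set are dropped; empty sets are dropped with
#' a warning; a line with fewer than three fields is an error.
#'
#' @param path GMT file path.
#' @param library_name Label for the library; defaults to the file name without
#'   extension.
#' @return A tibble with columns `set_name`, `description`, `gene` (one row per
#'   set membership) and attribute `library_name`.
#' @export
read_gmt <- function(path, library_name = NULL) {
  if (is.null(library_name)) {
    library_name <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need set name, description and >=1 gene",
                   i, length(fields)), call. = FALSE)
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      warning(sprintf("GMT line %d (set \"%s\") has no genes; set dropped", i, fields[1]),
              call. = FALSE)
      next
    }
    out[[i]] <- tibble::tibble(set_name = fields[1], description = fields[2],
                               gene = genes)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(set_name = character(), description = character(),
                          gene = character())
  }
  attr(res, "library_name") <- library_name
  res
}

#' Write a gene-set library in GMT format
#'
#' @param sets Long tibble as returned by [read_gmt()] (columns `set_name`,
#'   `description`, `gene`), or a named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (is.list(sets) && !is.data.frame(sets)) {
    sets <- purrr::imap_dfr(sets, function(g, nm) {
      tibble::tibble(set_name = nm, description = nm, gene = g)
    })
  }
  lines <- sets |>
    dplyr::summarise(line = paste(c(.data$set_name[1], .data$description[1],
                                    unique(.data$gene)), collapse = "\t"),
                     .by = "set_name")
  writeLines(lines$line, path)
  invisible(path)
}

#' Read a PPI interaction table, auto-detecting its dialect
#'
#' Two dialects are recognized by their columns: BioGRID-like tables carry
#' `partner_a`, `partner_b`, `evidence_count`; HIPPIE-like tables carry
#' `partner_a`, `partner_b`, `score`.
#'
#' @param path TSV path.
#' @return The table as a tibble with an added `dialect` column
#'   (`"biogrid"` or `"hippie"`).
#' @export
read_ppi_table <- function(path) {
  tab <- read_tsv_quiet(path)
  base <- c("partner_a", "partner_b")
  missing_base <- setdiff(base, names(tab))
  if (length(missing_base) > 0) {
    stop("PPI table lacks column(s): ", paste(missing_base, collapse = ", "),
         call. = FALSE)
  }
  if ("evidence_count" %in% names(tab)) {
    tab$dialect <- "biogrid"
  } else if ("score" %in% names(tab)) {
    tab$dialect <- "hippie"
  } else {
    stop("PPI table lacks column(s): evidence_count (BioGRID-like) or score (HIPPIE-like)",
         call. = FALSE)
  }
  tab
}

reg_dialect_requirements <- list(
  mirwalk    = list(cols = c("score", "region", "binding_gap"), types = c("mirna_gene", "mirna_tf")),
  mirsearch  = list(cols = "high_conf",   types = c("mirna_gene", "mirna_tf")),
  starbase   = list(cols = "score",       types = c("mirna_gene", "mirna_tf")),
  chipbase   = list(cols = "upstream_bp", types = "tf_gene"),
  itfp       = list(cols = character(),   types = "tf_gene"),
  enrichr_tf = list(cols = "evidence_p",  types = "tf_gene")
)

#' Read a typed regulatory edge table
#'
#' Regulatory edges are directed and typed (`mirna_gene`, `mirna_tf`,
#' `tf_gene`), carry a species tag (`human` / `mouse`), and per-dialect score
#' metadata emulating the exports of the source databases: miRWalk-like
#' (`score`, `region`, `binding_gap`), miRSearch-like (`high_conf`),
#' Starbase-like (`score`), ChIPBase-like (`upstream_bp`), ITFP-like (curated,
#' no score columns) and Enrichr-TF-like (`evidence_p`).
#'
#' @param path TSV path with columns `source`, `target`, `edge_type`,
#'   `species`, `dialect` plus the dialect's score columns.
#' @return Tibble of validated edges.
#' @export
read_reg_edges <- function(path) {
  tab <- read_tsv_quiet(path)
  need <- c("source", "target", "edge_type", "species", "dialect")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("regulatory edge table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_reg_edges(tab)
}

validate_reg_edges <- function(tab) {
  bad_dialect <- setdiff(unique(tab$dialect), names(reg_dialect_requirements))
  if (length(bad_dialect) > 0) {
    stop("unknown regulatory dialect(s): ", paste(bad_dialect, collapse = ", "),
         call. = FALSE)
  }
  bad_type <- setdiff(unique(tab$edge_type), c("mirna_gene", "mirna_tf", "tf_gene"))
  if (length(bad_type) > 0) {
    stop("unknown edge_type(s): ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  for (d in unique(tab$dialect)) {
    req <- reg_dialect_requirements[[d]]
    rows <- which(tab$dialect == d)
    wrong_type <- rows[!tab$edge_type[rows] %in% req$types]
    if (length(wrong_type) > 0) {
      stop(sprintf("row %d: edge_type \"%s\" not valid for dialect \"%s\"",
                   wrong_type[1], tab$edge_type[wrong_type[1]], d), call. = FALSE)
    }
    for (col in req$cols) {
      if (!col %in% names(tab)) {
        stop(sprintf("dialect \"%s\" requires column \"%s\"", d, col), call. = FALSE)
      }
      miss <- rows[is.na(tab[[col]][rows])]
      if (length(miss) > 0) {
        stop(sprintf("row %d: dialect \"%s\" requires a value in column \"%s\"",
                     miss[1], d, col), call. = FALSE)
      }
    }
  }
  self <- which(tab$source == tab$target)
  if (length(self) > 0) {
    stop(sprintf("row %d: self-edge %s -> %s not allowed",
                 self[1], tab$source[self[1]], tab$target[self[1]]), call. = FALSE)
  }
  tibble::as_tibble(tab)
}
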