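#' Per-triangle network label table
#'
#' One integer label per surface element, 0 meaning unassigned/medial wall.
#' The two hemispheres are held separately because the Yeo parcellations are
#' bilateral: the same label appears on both meshes.
#'
#' @param left,right integer vectors, one label in `0..17` per triangle.
#' @param names optional character vector naming labels `1..max`.
#' @return An object of class `label_table`.
#' @export
label_table <- function(left, right, names = NULL) {
  left <- as.integer(left); right <- as.integer(right)
  if (anyNA(left) || anyNA(right)) stop("labels must not be NA")
  if (min(c(left, right)) < 0L) stop("labels must be >= 0")
  n_lab <- max(c(left, right, 1L))
  if (n_lab > 17L) stop("label values above 17 are not supported")
  if (is.null(names)) names <- paste0("network_", seq_len(n_lab))
  structure(list(left = left, right = right, names = names), class = "label_table")
}

#' Read per-triangle labels from plain text
#'
#' Each file holds one integer per line (one per triangle, 0 = unassigned).
#'
#' @param left_path,right_path label file per hemisphere.
#' @return A [label_table()].
#' @export
read_labels <- function(left_path, right_path) {
  rd <- function(p) {
    if (!file.exists(p)) stop(sprintf("label file not found: %s", p))
    v <- scan(p, what = integer(), quiet = TRUE, comment.char = "#")
    v
  }
  label_table(rd(left_path), rd(right_path))
}

#' Write per-triangle labels as plain text (one integer per line)
#' @param labels a [label_table()].
#' @param left_path,right_path destination paths.
#' @export
write_labels <- function(labels, left_path, right_path) {
  writeLines(as.character(labels$left), left_path)
  writeLines(as.character(labels$right), right_path)
  invisible(NULL)
}

#' Read a 17-to-7 network weight mapping
#'
#' CSV with columns `network17`, `network7`, `weight`. Weights for each
#' 17-network must sum to 1 and every network 1..17 must appear. The package
#' ships an editable default in `inst/extdata/yeo17_to_yeo7_default.csv`
#' because any such mapping is approximate.
#'
#' @param path CSV path; `NULL` loads the shipped default.
#' @return data.frame with the three columns, validated.
#' @export
read_network_mapping <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "yeo17_to_yeo7_default.csv",
                        package = "transcallosal", mustWork = TRUE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("network17", "network7", "weight")
  if (!all(need %in% names(m)))
    stop(sprintf("mapping CSV must have columns %s", paste(need, collapse = ", ")))
  m$network17 <- as.integer(m$network17)
  m$network7 <- as.integer(m$network7)
  if (!setequal(unique(m$network17), 1:17))
    stop("mapping must cover every network 1..17")
  if (any(m$weight < 0)) stop("mapping weights must be non-negative")
  sums <- tapply(m$weight, m$network17, sum)
  if (any(abs(sums - 1) > 1e-8))
    stop("weights for each network17 must sum to 1")
  m
}
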