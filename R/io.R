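# Plain-text serialization: multi-frame XYZ for coordinates and
# trajectories, JSON for estimates and sampled-state metadata.

#' Write coordinates or a trajectory as (multi-frame) XYZ
#'
#' @param frames a single n x 3 matrix or a list of them.
#' @param elements element symbols.
#' @param path output file.
#' @param comment per-frame comment line(s).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, elements, path, comment = "") {
  if (is.matrix(frames)) frames <- list(frames)
  comment <- rep_len(comment, length(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    x <- frames[[f]]
    writeLines(as.character(nrow(x)), con)
    writeLines(comment[f], con)
    writeLines(sprintf("%-3s %16.8f %16.8f %16.8f",
                       elements, x[, 1], x[, 2], x[, 3]), con)
  }
  invisible(path)
}

#' Read a (multi-frame) XYZ file
#'
#' @param path XYZ file.
#' @return list with `elements` and `frames` (list of n x 3 matrices) and
#'   `comments`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  comments <- character(0)
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    comments <- c(comments, lines[i + 1L])
    block <- lines[i + 1L + seq_len(n)]
    parts <- strsplit(trimws(block), "\\s+")
    el <- vapply(parts, `[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  list(elements = elements, frames = frames, comments = comments)
}

#' Serialize a free-energy estimate to JSON
#'
#' @param est an `fe_estimate` (or list of them).
#' @param path output file.
#' @param meta optional named list of extra metadata (seeds, protocol
#'   hash, pair name).
#' @return `path`, invisibly.
#' @export
write_estimate <- function(est, path, meta = list()) {
  one <- function(e) list(f_hat = e$f_hat, dG = e$dG, sigma = e$sigma,
                          ess = e$ess, lambdas = e$lambdas,
                          overlap_warning = e$overlap_warning)
  obj <- if (inherits(est, "fe_estimate")) one(est) else lapply(est, one)
  jsonlite::write_json(c(obj, meta), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export sampled states as XYZ plus a JSON sidecar
#'
#' @param states a `sampled_states`.
#' @param system the hybrid system (for element symbols).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the sidecar path, invisibly.
#' @export
write_sampled_states <- function(states, system, dir, prefix = "states") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(states$replicates)) {
    for (m in seq_along(states$lambdas)) {
      fr <- states$replicates[[r]]$snapshots[[m]]$frames
      frames <- lapply(seq_len(dim(fr)[3]), function(s) fr[, , s])
      write_xyz(frames, system$elements,
                file.path(dir, sprintf("%s_r%d_l%02d.xyz", prefix, r, m)),
                comment = sprintf("lambda=%.4f replicate=%d",
                                  states$lambdas[m], r))
    }
  }
  sidecar <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(
    list(lambdas = states$lambdas, master_seed = states$master_seed,
         protocol = unclass(states$protocol),
         replicate_seeds = lapply(states$replicates, `[[`, "seeds")),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}
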