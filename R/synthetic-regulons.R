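#' Generate the synthetic regulon set
#'
#' Builds the regulon records for the planted fate TFs (targets = their
#' configured fate signature genes, NES >= 1 so they survive the inclusion
#' filter) and decoy TFs (random background targets, NES < 1).
#'
#' @param config a [sim_config()].
#' @return A [regulon_set()].
#' @export
generate_regulons <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(config$planted_regulons)) stop("planted_regulons is empty")
  lay <- config$layout
  recs <- with_seed(config$seed + 400L, {
    lapply(seq_along(config$planted_regulons), function(k) {
      r <- config$planted_regulons[[k]]
      planted <- r$fate %in% c("proximal", "distal")
      targets <- r$targets
      if (is.null(targets)) {
        targets <- sample(lay$background, 10L)
      }
      list(tf = config$gene_names[r$tf],
           nes = if (planted) round(runif(1, 1.5, 3), 3) else round(runif(1, 0.2, 0.9), 3),
           targets = config$gene_names[targets])
    })
  })
  regulon_set(recs)
}

#' Regulon set container
#'
#' @param records list of records, each `list(tf, nes, targets)`; `nes` may
#'   be `NA`.
#' @return An object of class `regulon_set`.
#' @export
regulon_set <- function(records) {
  tfs <- vapply(records, `[[`, character(1), "tf")
  if (anyDuplicated(tfs)) {
    stop("duplicate TF names: ", paste(unique(tfs[duplicated(tfs)]), collapse = ", "))
  }
  for (r in records) {
    if (!length(r$targets)) stop("regulon ", r$tf, " has no targets")
  }
  structure(list(records = records), class = "regulon_set")
}

#' @export
print.regulon_set <- function(x, ...) {
  cat(sprintf("regulon_set: %d regulons\n", length(x$records)))
  for (r in utils::head(x$records, 5)) {
    cat(sprintf("  %s (NES %s): %d targets\n", r$tf,
                format(r$nes), length(r$targets)))
  }
  if (length(x$records) > 5) cat("  ...\n")
  invisible(x)
}

#' @export
length.regulon_set <- function(x) length(x$records)

#' Read / write regulons as GMT
#'
#' GMT dialect: one tab-separated record per regulon; column 1 = TF name,
#' column 2 = NES (the string "NA" for regulons without one), columns 3+ =
#' target gene symbols.
#'
#' @param path file path.
#' @return `read_regulons_gmt`: a [regulon_set()].
#' @export
read_regulons_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line (need tf, NES, >=1 target): ", l)
    list(tf = f[1],
         nes = if (f[2] == "NA") NA_real_ else as.numeric(f[2]),
         targets = f[-(1:2)])
  })
  regulon_set(recs)
}

#' @rdname read_regulons_gmt
#' @param regulons a [regulon_set()].
#' @return `write_regulons_gmt`: invisibly, `path`.
#' @export
write_regulons_gmt <- function(regulons, path) {
  stopifnot(inherits(regulons, "regulon_set"))
  lines <- vapply(regulons$records, function(r) {
    paste(c(r$tf, ifelse(is.na(r$nes), "NA", format(r$nes)), r$targets),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
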