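#' Write a cohort to disk
#'
#' One 8-bit grayscale PNG per eye per plexus plus a `cohort.csv` table with
#' columns `patient_id, eye, label, sex, age, plexus, file`. The CSV is a
#' deterministic function of the cohort.
#'
#' @param cohort an `octa_cohort`.
#' @param dir output directory (created if missing).
#' @return the path of the cohort table, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "octa_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (rec in cohort) {
    for (pl in names(rec$images)) {
      file <- sprintf("%s_%s_%s.png", rec$patient_id, rec$eye, pl)
      png::writePNG(rec$images[[pl]]$pixels, file.path(dir, file))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = rec$patient_id, eye = rec$eye, label = rec$label,
        sex = rec$sex, age = rec$age, plexus = pl, file = file,
        row.names = NULL)
    }
  }
  tab <- do.call(rbind, rows)
  path <- file.path(dir, "cohort.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `cohort.csv` and the PNG images.
#' @param pixel_size_mm physical pixel size of the stored images.
#' @return an `octa_cohort` (8-bit quantized pixels).
#' @export
read_cohort <- function(dir, pixel_size_mm = 0.0057) {
  tab <- utils::read.csv(file.path(dir, "cohort.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character",
                                        eye = "character", label = "character",
                                        sex = "character", age = "numeric",
                                        plexus = "character",
                                        file = "character"))
  keys <- unique(tab[c("patient_id", "eye")])
  cohort <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- tab[tab$patient_id == keys$patient_id[i] & tab$eye == keys$eye[i], ]
    images <- list()
    for (j in seq_len(nrow(sub))) {
      px <- png::readPNG(file.path(dir, sub$file[j]))
      if (length(dim(px)) == 3L) px <- px[, , 1]
      images[[sub$plexus[j]]] <- angiogram(px, pixel_size_mm = pixel_size_mm)
    }
    cohort[[i]] <- structure(
      list(patient_id = sub$patient_id[1], eye = sub$eye[1],
           label = sub$label[1], sex = sub$sex[1], age = sub$age[1],
           images = images),
      class = "eye_record")
  }
  structure(cohort, class = "octa_cohort")
}

#' Write per-eye, per-region vessel densities to CSV
#'
#' Long format: `patient_id, eye, label, plexus, region, vd`.
#'
#' @param features a [cohort_features()] result.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_vd_csv <- function(features, path) {
  tab <- features$table
  rows <- list()
  for (m in names(features$methods)) {
    parts <- strsplit(m, ".", fixed = TRUE)[[1]]
    x <- features$methods[[m]]
    for (rg in colnames(x)) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = tab$patient_id, eye = tab$eye, label = tab$label,
        plexus = parts[1], region = rg, vd = x[, rg], row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$eye, out$plexus, out$region), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the experiment metrics table and pairwise comparisons to CSV
#'
#' @param experiment a `vd_experiment`.
#' @param dir output directory.
#' @return paths of the written files, invisibly.
#' @export
write_results_csv <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "metrics.csv")
  utils::write.csv(results_table(experiment), p1, row.names = FALSE)
  p2 <- file.path(dir, "pairwise.csv")
  utils::write.csv(experiment$pairwise$pairs, p2, row.names = FALSE)
  p3 <- file.path(dir, "manifest.json")
  jsonlite::write_json(experiment$manifest, p3, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(metrics = p1, pairwise = p2, manifest = p3))
}
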