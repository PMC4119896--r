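# Plain-text I/O for the CSV/JSON dialects the scoring modules exchange.

#' Read and write 3D landmark tables
#'
#' Long CSV dialect: columns `case_id`, `side`, `landmark` (`cusp_tip` or
#' `root_apex`), `x_mm`, `y_mm`, `z_mm`; one row per landmark, two rows per
#' canine.
#'
#' @param path CSV file path.
#' @return `read_landmarks` returns a list of [canine_case()] objects;
#'   `write_landmarks` returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "side", "landmark", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stop(sprintf("landmark CSV needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  lapply(split(df, df$case_id)[unique(df$case_id)], function(g) {
    cusp <- g[g$landmark == "cusp_tip", ]
    apex <- g[g$landmark == "root_apex", ]
    if (nrow(cusp) != 1L || nrow(apex) != 1L) {
      stop(sprintf("case '%s' must have exactly one cusp_tip and one root_apex row",
                   g$case_id[1]), call. = FALSE)
    }
    canine_case(g$case_id[1], g$side[1],
                c(cusp$x_mm, cusp$y_mm, cusp$z_mm),
                c(apex$x_mm, apex$y_mm, apex$z_mm))
  })
}

#' @rdname read_landmarks
#' @param cases list of [canine_case()] objects.
#' @export
write_landmarks <- function(cases, path) {
  rows <- lapply(cases, function(cs) {
    data.frame(case_id = cs$case_id, side = cs$side,
               landmark = c("cusp_tip", "root_apex"),
               x_mm = c(cs$cusp_tip[1], cs$root_apex[1]),
               y_mm = c(cs$cusp_tip[2], cs$root_apex[2]),
               z_mm = c(cs$cusp_tip[3], cs$root_apex[3]),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read and write panoramic (2D) case tables
#'
#' Wide CSV dialect: `case_id` plus named 2D landmarks in mm (`cusp_x`,
#' `cusp_y`, `apex_x`, `apex_y`, `occ_molar_x/y`, `occ_incisor_x/y`,
#' `midline_top_x/y`, `midline_bottom_x/y`) and the four sector boundary x
#' positions `sector_b1`..`sector_b4`.
#'
#' @param path CSV file path.
#' @return `read_cases_2d` returns a list of [panoramic_case()] objects;
#'   `write_cases_2d` returns `path` invisibly.
#' @export
read_cases_2d <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    panoramic_case(r$case_id,
                   cusp_tip = c(r$cusp_x, r$cusp_y),
                   root_apex = c(r$apex_x, r$apex_y),
                   occlusal_ref_molar = c(r$occ_molar_x, r$occ_molar_y),
                   occlusal_ref_incisor = c(r$occ_incisor_x, r$occ_incisor_y),
                   midline_top = c(r$midline_top_x, r$midline_top_y),
                   midline_bottom = c(r$midline_bottom_x, r$midline_bottom_y),
                   sector_boundaries = c(r$sector_b1, r$sector_b2,
                                         r$sector_b3, r$sector_b4))
  })
}

#' @rdname read_cases_2d
#' @param cases list of [panoramic_case()] objects.
#' @export
write_cases_2d <- function(cases, path) {
  rows <- lapply(cases, function(cs) {
    data.frame(case_id = cs$case_id,
               cusp_x = cs$cusp_tip[1], cusp_y = cs$cusp_tip[2],
               apex_x = cs$root_apex[1], apex_y = cs$root_apex[2],
               occ_molar_x = cs$occlusal_ref_molar[1],
               occ_molar_y = cs$occlusal_ref_molar[2],
               occ_incisor_x = cs$occlusal_ref_incisor[1],
               occ_incisor_y = cs$occlusal_ref_incisor[2],
               midline_top_x = cs$midline_top[1], midline_top_y = cs$midline_top[2],
               midline_bottom_x = cs$midline_bottom[1],
               midline_bottom_y = cs$midline_bottom[2],
               sector_b1 = cs$sector_boundaries[1], sector_b2 = cs$sector_boundaries[2],
               sector_b3 = cs$sector_boundaries[3], sector_b4 = cs$sector_boundaries[4],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a KPG score table as CSV
#'
#' One row per case: `case_id`, the six subscores `Cx`..`Rz`, `total` and the
#' three category labels, as produced by [score_cases()].
#'
#' @param scores data.frame from [score_cases()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' Read and write rating panels as CSV
#'
#' @param path CSV file path.
#' @return `read_panel` returns a [rating_panel()]; `write_panel` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  rating_panel(utils::read.csv(path, stringsAsFactors = FALSE,
                               colClasses = "character"))
}

#' @rdname read_panel
#' @param panel a [rating_panel()].
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Read and write 2x2 contingency tables
#'
#' JSON dialect: object with `rows`, `cols` (label arrays), `counts` (2x2
#' array) and optional `row_index` / `col_index` names. CSV dialect: header
#' row of column labels, two data rows with the row label in the first
#' column.
#'
#' @param path file path; format inferred from the extension
#'   (`.json` or `.csv`).
#' @return `read_table_2x2` returns a [contingency_2x2()];
#'   `write_table_2x2` returns `path` invisibly.
#' @export
read_table_2x2 <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    contingency_2x2(x$counts, x$rows, x$cols,
                    if (is.null(x$row_index)) "A" else x$row_index,
                    if (is.null(x$col_index)) "B" else x$col_index)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    contingency_2x2(counts, df[[1]], colnames(df)[-1])
  }
}

#' @rdname read_table_2x2
#' @param table a [contingency_2x2()].
#' @export
write_table_2x2 <- function(table, path) {
  stopifnot(inherits(table, "contingency_2x2"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(rows = rownames(table$counts),
                              cols = colnames(table$counts),
                              counts = unname(unclass(table$counts)),
                              row_index = table$row_index,
                              col_index = table$col_index),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    df <- data.frame(label = rownames(table$counts), table$counts,
                     check.names = FALSE)
    names(df)[1] <- ""
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Write an anatomy frame as JSON
#'
#' @param frame an [anatomy_frame()].
#' @param path JSON file path.
#' @return `path` invisibly; `read_frame` returns the restored
#'   [anatomy_frame()].
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "anatomy_frame"))
  jsonlite::write_json(lapply(unclass(frame), function(x) {
    if (is.matrix(x)) unname(x) else unname(as.numeric(x))
  }), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  anatomy_frame(x$midsagittal_x, x$occlusal_points, x$arch_curve,
                x$ideal_cusp, x$ideal_apex,
                x$lateral_distal_x, x$lateral_midline_x,
                x$lateral_mesial_x, x$central_midline_x)
}
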