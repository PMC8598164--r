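# Small in-code fixtures shared across test files.

tiny_library <- function() {
  guide_library(
    guide_id = c(paste0("gA_", 1:2), paste0("gB_", 1:2), paste0("NTC_", 1:2)),
    gene = c("A", "A", "B", "B", "NTC", "NTC")
  )
}

tiny_sheet <- function() {
  sample_sheet(
    sample_id = c("input_r1", "MHCII_high_r1", "MHCII_low_r1"),
    marker = c(NA, "MHCII", "MHCII"),
    replicate = c(1L, 1L, 1L),
    bin = c("input", "high", "low")
  )
}

tiny_screen <- function(counts = NULL) {
  lib <- tiny_library()
  sheet <- tiny_sheet()
  if (is.null(counts)) {
    counts <- matrix(
      c(100, 120, 80,
        110, 100, 90,
        90, 40, 160,
        105, 50, 150,
        100, 100, 100,
        95, 95, 95),
      nrow = 6, byrow = TRUE,
      dimnames = list(lib$guide_id, sheet$sample_id)
    )
  }
  screen_counts(counts, lib, sheet)
}

# restrict a screen to one marker's sorted samples (keeping inputs)
subset_screen <- function(sc, marker) {
  keep <- is.na(sc$samples$marker) | sc$samples$marker == marker
  screen_counts(sc$counts[, sc$samples$sample_id[keep], drop = FALSE],
                sc$library, sc$samples[keep, , drop = FALSE])
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
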