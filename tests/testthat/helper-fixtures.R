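# Small in-code fixtures shared across test files.

six_stages <- c("ESC", "MES", "HB", "HE", "HP", "MAC")

make_expr <- function(rows, stages = NULL) {
  m <- do.call(rbind, rows)
  colnames(m) <- stages %||% six_stages[seq_len(ncol(m))]
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

tiny_interactions <- function(lines) {
  read_interactions(write_tsv_lines(lines))
}

# interaction table built directly (bypasses file round trip)
itab <- function(regulator, target, mode = "Unknown") {
  tab <- data.frame(regulator = regulator, target = target,
                    mode = rep_len(mode, length(regulator)),
                    stringsAsFactors = FALSE)
  tab$evidence <- rep(list("1"), nrow(tab))
  class(tab) <- c("interaction_table", "data.frame")
  tab
}
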