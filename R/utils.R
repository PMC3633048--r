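# Accept either a path to an existing file or literal text (single string
# with newlines, or a character vector of lines).
read_lines_or_text <- function(path) {
  if (length(path) == 1 && !grepl("\n", path, fixed = TRUE) &&
      file.exists(path)) {
    return(readLines(path, warn = FALSE))
  }
  unlist(strsplit(paste(path, collapse = "\n"), "\n", fixed = TRUE))
}
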