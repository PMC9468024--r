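# Minimal 3x5 bitmap glyphs for rendering confidence values onto overlays.
.glyphs <- local({
  g <- list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "010", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111"),
    "." = c("000", "000", "000", "000", "010")
  )
  lapply(g, function(rows) {
    do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
  })
})

# Draw `text` (digits and dots) centred at (row, col) onto an [H, W, 3]
# array, scaled by an integer factor, in the given colour.
draw_text <- function(img, text, row, col, scale = 2L, color = c(0, 0, 0)) {
  chars <- strsplit(text, "")[[1]]
  glyph_w <- 3L * scale + scale # including 1-glyph spacing
  total_w <- length(chars) * glyph_w - scale
  total_h <- 5L * scale
  r0 <- round(row - total_h / 2); c0 <- round(col - total_w / 2)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  for (i in seq_along(chars)) {
    gl <- .glyphs[[chars[i]]]
    if (is.null(gl)) next
    big <- gl[rep(seq_len(5L), each = scale), rep(seq_len(3L), each = scale)]
    rows <- r0 + seq_len(nrow(big)) - 1L
    cols <- c0 + (i - 1L) * glyph_w + seq_len(ncol(big)) - 1L
    ok_r <- rows >= 1L & rows <= h
    ok_c <- cols >= 1L & cols <= w
    if (!any(ok_r) || !any(ok_c)) next
    sub <- big[ok_r, ok_c, drop = FALSE]
    for (ch in 1:3) {
      plane <- img[rows[ok_r], cols[ok_c], ch]
      plane[sub == 1L] <- color[ch]
      img[rows[ok_r], cols[ok_c], ch] <- plane
    }
  }
  img
}
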