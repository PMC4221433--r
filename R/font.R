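# A package-defined 5x7 bitmap font (ASCII subset). Rendering text straight
# into the raster keeps exports byte-identical across machines: no system
# font, no font library, no antialiasing. Each glyph is 7 rows of 5 cells,
# 'X' = inked, '.' = blank, stored as one 35-character string.

glyph_rows <- function(...) paste0(c(...), collapse = "")

font_5x7 <- local({
  g <- list(
    " " = glyph_rows(".....", ".....", ".....", ".....", ".....", ".....", "....."),
    "A" = glyph_rows(".XXX.", "X...X", "X...X", "XXXXX", "X...X", "X...X", "X...X"),
    "B" = glyph_rows("XXXX.", "X...X", "X...X", "XXXX.", "X...X", "X...X", "XXXX."),
    "C" = glyph_rows(".XXX.", "X...X", "X....", "X....", "X....", "X...X", ".XXX."),
    "D" = glyph_rows("XXXX.", "X...X", "X...X", "X...X", "X...X", "X...X", "XXXX."),
    "E" = glyph_rows("XXXXX", "X....", "X....", "XXXX.", "X....", "X....", "XXXXX"),
    "F" = glyph_rows("XXXXX", "X....", "X....", "XXXX.", "X....", "X....", "X...."),
    "G" = glyph_rows(".XXX.", "X...X", "X....", "X.XXX", "X...X", "X...X", ".XXX."),
    "H" = glyph_rows("X...X", "X...X", "X...X", "XXXXX", "X...X", "X...X", "X...X"),
    "I" = glyph_rows(".XXX.", "..X..", "..X..", "..X..", "..X..", "..X..", ".XXX."),
    "J" = glyph_rows("..XXX", "...X.", "...X.", "...X.", "...X.", "X..X.", ".XX.."),
    "K" = glyph_rows("X...X", "X..X.", "X.X..", "XX...", "X.X..", "X..X.", "X...X"),
    "L" = glyph_rows("X....", "X....", "X....", "X....", "X....", "X....", "XXXXX"),
    "M" = glyph_rows("X...X", "XX.XX", "X.X.X", "X.X.X", "X...X", "X...X", "X...X"),
    "N" = glyph_rows("X...X", "XX..X", "X.X.X", "X..XX", "X...X", "X...X", "X...X"),
    "O" = glyph_rows(".XXX.", "X...X", "X...X", "X...X", "X...X", "X...X", ".XXX."),
    "P" = glyph_rows("XXXX.", "X...X", "X...X", "XXXX.", "X....", "X....", "X...."),
    "Q" = glyph_rows(".XXX.", "X...X", "X...X", "X...X", "X.X.X", "X..X.", ".XX.X"),
    "R" = glyph_rows("XXXX.", "X...X", "X...X", "XXXX.", "X.X..", "X..X.", "X...X"),
    "S" = glyph_rows(".XXXX", "X....", "X....", ".XXX.", "....X", "....X", "XXXX."),
    "T" = glyph_rows("XXXXX", "..X..", "..X..", "..X..", "..X..", "..X..", "..X.."),
    "U" = glyph_rows("X...X", "X...X", "X...X", "X...X", "X...X", "X...X", ".XXX."),
    "V" = glyph_rows("X...X", "X...X", "X...X", "X...X", "X...X", ".X.X.", "..X.."),
    "W" = glyph_rows("X...X", "X...X", "X...X", "X.X.X", "X.X.X", "XX.XX", "X...X"),
    "X" = glyph_rows("X...X", "X...X", ".X.X.", "..X..", ".X.X.", "X...X", "X...X"),
    "Y" = glyph_rows("X...X", "X...X", ".X.X.", "..X..", "..X..", "..X..", "..X.."),
    "Z" = glyph_rows("XXXXX", "....X", "...X.", "..X..", ".X...", "X....", "XXXXX"),
    "a" = glyph_rows(".....", ".....", ".XXX.", "....X", ".XXXX", "X...X", ".XXXX"),
    "b" = glyph_rows("X....", "X....", "XXXX.", "X...X", "X...X", "X...X", "XXXX."),
    "c" = glyph_rows(".....", ".....", ".XXXX", "X....", "X....", "X....", ".XXXX"),
    "d" = glyph_rows("....X", "....X", ".XXXX", "X...X", "X...X", "X...X", ".XXXX"),
    "e" = glyph_rows(".....", ".....", ".XXX.", "X...X", "XXXXX", "X....", ".XXXX"),
    "f" = glyph_rows("..XX.", ".X..X", ".X...", "XXX..", ".X...", ".X...", ".X..."),
    "g" = glyph_rows(".....", ".XXXX", "X...X", "X...X", ".XXXX", "....X", ".XXX."),
    "h" = glyph_rows("X....", "X....", "XXXX.", "X...X", "X...X", "X...X", "X...X"),
    "i" = glyph_rows("..X..", ".....", ".XX..", "..X..", "..X..", "..X..", ".XXX."),
    "j" = glyph_rows("...X.", ".....", "...X.", "...X.", "...X.", "X..X.", ".XX.."),
    "k" = glyph_rows("X....", "X....", "X..X.", "X.X..", "XX...", "X.X..", "X..X."),
    "l" = glyph_rows(".XX..", "..X..", "..X..", "..X..", "..X..", "..X..", ".XXX."),
    "m" = glyph_rows(".....", ".....", "XX.X.", "X.X.X", "X.X.X", "X.X.X", "X...X"),
    "n" = glyph_rows(".....", ".....", "XXXX.", "X...X", "X...X", "X...X", "X...X"),
    "o" = glyph_rows(".....", ".....", ".XXX.", "X...X", "X...X", "X...X", ".XXX."),
    "p" = glyph_rows(".....", "XXXX.", "X...X", "X...X", "XXXX.", "X....", "X...."),
    "q" = glyph_rows(".....", ".XXXX", "X...X", "X...X", ".XXXX", "....X", "....X"),
    "r" = glyph_rows(".....", ".....", "X.XX.", "XX..X", "X....", "X....", "X...."),
    "s" = glyph_rows(".....", ".....", ".XXXX", "X....", ".XXX.", "....X", "XXXX."),
    "t" = glyph_rows(".X...", ".X...", "XXX..", ".X...", ".X...", ".X..X", "..XX."),
    "u" = glyph_rows(".....", ".....", "X...X", "X...X", "X...X", "X..XX", ".XX.X"),
    "v" = glyph_rows(".....", ".....", "X...X", "X...X", "X...X", ".X.X.", "..X.."),
    "w" = glyph_rows(".....", ".....", "X...X", "X...X", "X.X.X", "X.X.X", ".X.X."),
    "x" = glyph_rows(".....", ".....", "X...X", ".X.X.", "..X..", ".X.X.", "X...X"),
    "y" = glyph_rows(".....", "X...X", "X...X", ".XXXX", "....X", "X...X", ".XXX."),
    "z" = glyph_rows(".....", ".....", "XXXXX", "...X.", "..X..", ".X...", "XXXXX"),
    "0" = glyph_rows(".XXX.", "X...X", "X..XX", "X.X.X", "XX..X", "X...X", ".XXX."),
    "1" = glyph_rows("..X..", ".XX..", "..X..", "..X..", "..X..", "..X..", ".XXX."),
    "2" = glyph_rows(".XXX.", "X...X", "....X", "...X.", "..X..", ".X...", "XXXXX"),
    "3" = glyph_rows(".XXX.", "X...X", "....X", "..XX.", "....X", "X...X", ".XXX."),
    "4" = glyph_rows("...X.", "..XX.", ".X.X.", "X..X.", "XXXXX", "...X.", "...X."),
    "5" = glyph_rows("XXXXX", "X....", "XXXX.", "....X", "....X", "X...X", ".XXX."),
    "6" = glyph_rows(".XXX.", "X....", "X....", "XXXX.", "X...X", "X...X", ".XXX."),
    "7" = glyph_rows("XXXXX", "....X", "...X.", "..X..", ".X...", ".X...", ".X..."),
    "8" = glyph_rows(".XXX.", "X...X", "X...X", ".XXX.", "X...X", "X...X", ".XXX."),
    "9" = glyph_rows(".XXX.", "X...X", "X...X", ".XXXX", "....X", "....X", ".XXX."),
    "." = glyph_rows(".....", ".....", ".....", ".....", ".....", ".XX..", ".XX.."),
    "," = glyph_rows(".....", ".....", ".....", ".....", ".....", "..X..", ".X..."),
    "-" = glyph_rows(".....", ".....", ".....", "XXXXX", ".....", ".....", "....."),
    "_" = glyph_rows(".....", ".....", ".....", ".....", ".....", ".....", "XXXXX"),
    "(" = glyph_rows("...X.", "..X..", ".X...", ".X...", ".X...", "..X..", "...X."),
    ")" = glyph_rows(".X...", "..X..", "...X.", "...X.", "...X.", "..X..", ".X..."),
    "[" = glyph_rows(".XXX.", ".X...", ".X...", ".X...", ".X...", ".X...", ".XXX."),
    "]" = glyph_rows(".XXX.", "...X.", "...X.", "...X.", "...X.", "...X.", ".XXX."),
    "/" = glyph_rows("....X", "....X", "...X.", "..X..", ".X...", "X....", "X...."),
    "+" = glyph_rows(".....", "..X..", "..X..", "XXXXX", "..X..", "..X..", "....."),
    ":" = glyph_rows(".....", "..X..", "..X..", ".....", "..X..", "..X..", "....."),
    "#" = glyph_rows(".X.X.", ".X.X.", "XXXXX", ".X.X.", "XXXXX", ".X.X.", ".X.X."),
    "%" = glyph_rows("XX..X", "XX..X", "...X.", "..X..", ".X...", "X..XX", "X..XX"),
    "*" = glyph_rows(".....", ".X.X.", "..X..", "XXXXX", "..X..", ".X.X.", "....."),
    "=" = glyph_rows(".....", ".....", "XXXXX", ".....", "XXXXX", ".....", "....."),
    "'" = glyph_rows("..X..", "..X..", ".....", ".....", ".....", ".....", "....."),
    "!" = glyph_rows("..X..", "..X..", "..X..", "..X..", "..X..", ".....", "..X.."),
    "?" = glyph_rows(".XXX.", "X...X", "....X", "..XX.", "..X..", ".....", "..X.."),
    "<" = glyph_rows("...X.", "..X..", ".X...", "X....", ".X...", "..X..", "...X."),
    ">" = glyph_rows(".X...", "..X..", "...X.", "....X", "...X.", "..X..", ".X..."),
    "\"" = glyph_rows(".X.X.", ".X.X.", ".....", ".....", ".....", ".....", ".....")
  )
  lapply(g, function(s) {
    matrix(strsplit(s, "")[[1]] == "X", nrow = 7L, byrow = TRUE)
  })
})

# fallback for glyphs outside the table: a hollow box
font_fallback <- matrix(strsplit(glyph_rows(
  "XXXXX", "X...X", "X...X", "X...X", "X...X", "X...X", "XXXXX"),
  "")[[1]] == "X", nrow = 7L, byrow = TRUE)

glyph_w <- 5L
glyph_h <- 7L
glyph_advance <- 6L   # 5 px glyph + 1 px spacing

# Logical pixel mask (rows x cols) of a text string at scale 1.
text_mask <- function(text) {
  chars <- strsplit(text, "")[[1]]
  if (length(chars) == 0L) return(matrix(FALSE, glyph_h, 0L))
  w <- length(chars) * glyph_advance - 1L
  m <- matrix(FALSE, glyph_h, w)
  x <- 0L
  for (ch in chars) {
    gm <- font_5x7[[ch]]
    if (is.null(gm)) gm <- font_fallback
    m[, (x + 1L):(x + glyph_w)] <- m[, (x + 1L):(x + glyph_w)] | gm
    x <- x + glyph_advance
  }
  m
}

# Pixel width/height of a rendered string at angle 0/45/90 degrees.
text_extent <- function(text, angle = 0L) {
  n <- nchar(text)
  w <- if (n > 0L) n * glyph_advance - 1L else 0L
  h <- glyph_h
  if (angle == 90L) c(w = h, h = w)
  else if (angle == 45L) {
    d <- ceiling((w + h) / sqrt(2))
    c(w = d, h = d)
  } else c(w = w, h = h)
}
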