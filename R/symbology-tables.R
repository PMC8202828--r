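# Symbol tables shared by the encoder (synthetic rendering) and the line-scan
# decoders.
#
# Code 128: 107 symbols (values 0..102 data, 103/104/105 the three start
# codes), each 3 bars + 3 spaces totalling 11 modules; the stop pattern is
# 4 bars + 3 spaces totalling 13 modules. Widths are listed bar-first.
#
# Code 39: 43 data characters plus the '*' delimiter, each 5 bars + 4 spaces
# of which exactly 3 elements are wide.

CODE128_WIDTH_STRINGS <- c(
  "212222", "222122", "222221", "121223", "121322", "131222", "122213",
  "122312", "132212", "221213", "221312", "231212", "112232", "122132",
  "122231", "113222", "123122", "123221", "223211", "221132", "221231",
  "213212", "223112", "312131", "311222", "321122", "321221", "312212",
  "322112", "322211", "212123", "212321", "232121", "111323", "131123",
  "131321", "112313", "132113", "132311", "211313", "231113", "231311",
  "112133", "112331", "132131", "113123", "113321", "133121", "313121",
  "211331", "231131", "213113", "213311", "213131", "311123", "311321",
  "331121", "312113", "312311", "332111", "314111", "221411", "431111",
  "111224", "111422", "121124", "121421", "141122", "141221", "112214",
  "112412", "122114", "122411", "142112", "142211", "241211", "221114",
  "413111", "241112", "134111", "111242", "121142", "121241", "114212",
  "124112", "124211", "411212", "421112", "421211", "212141", "214121",
  "412121", "111143", "111341", "131141", "114113", "114311", "411113",
  "411311", "113141", "114131", "311141", "411131", "211412", "211214",
  "211232"
)

# 106 x 6 integer matrix, row i = symbol value i - 1 (values 0..105)
CODE128_WIDTHS <- do.call(rbind, lapply(strsplit(CODE128_WIDTH_STRINGS, ""),
                                        as.integer))

# adjacent-pair sums (leading-edge-to-leading-edge distances in modules):
# invariant to displacement of the shared edge, hence robust to the cell
# quantization of the rasterized scanline
CODE128_EDGE_SUMS <- CODE128_WIDTHS[, 1:5] + CODE128_WIDTHS[, 2:6]

CODE128_STOP <- c(2L, 3L, 3L, 1L, 1L, 1L, 2L)

CODE128_START_A <- 103L
CODE128_START_B <- 104L
CODE128_START_C <- 105L
CODE128_CODE_TO_C <- 99L   # switch to set C (from A or B)
CODE128_CODE_TO_B <- 100L  # switch to set B (from A or C)
CODE128_CODE_TO_A <- 101L  # switch to set A (from B or C)
CODE128_SHIFT <- 98L

# Code set B: values 0..94 map to ASCII 32..126.
code128_b_char <- function(v) rawToChar(as.raw(v + 32L))
code128_b_value <- function(ch) as.integer(charToRaw(ch)) - 32L

# Code set A: values 0..63 map to ASCII 32..95, values 64..95 to ASCII 0..31.
code128_a_char <- function(v) {
  if (v <= 63L) rawToChar(as.raw(v + 32L)) else rawToChar(as.raw(v - 64L))
}

# Code 39 patterns: 9 characters per element string, alternating
# bar/space/bar/... starting and ending with a bar; N = narrow, W = wide.
CODE39_PATTERNS <- c(
  "0" = "NNNWWNWNN", "1" = "WNNWNNNNW", "2" = "NNWWNNNNW", "3" = "WNWWNNNNN",
  "4" = "NNNWWNNNW", "5" = "WNNWWNNNN", "6" = "NNWWWNNNN", "7" = "NNNWNNWNW",
  "8" = "WNNWNNWNN", "9" = "NNWWNNWNN",
  "A" = "WNNNNWNNW", "B" = "NNWNNWNNW", "C" = "WNWNNWNNN", "D" = "NNNNWWNNW",
  "E" = "WNNNWWNNN", "F" = "NNWNWWNNN", "G" = "NNNNNWWNW", "H" = "WNNNNWWNN",
  "I" = "NNWNNWWNN", "J" = "NNNNWWWNN", "K" = "WNNNNNNWW", "L" = "NNWNNNNWW",
  "M" = "WNWNNNNWN", "N" = "NNNNWNNWW", "O" = "WNNNWNNWN", "P" = "NNWNWNNWN",
  "Q" = "NNNNNNWWW", "R" = "WNNNNNWWN", "S" = "NNWNNNWWN", "T" = "NNNNWNWWN",
  "U" = "WWNNNNNNW", "V" = "NWWNNNNNW", "W" = "WWWNNNNNN", "X" = "NWNNWNNNW",
  "Y" = "WWNNWNNNN", "Z" = "NWWNWNNNN",
  "-" = "NWNNNNWNW", "." = "WWNNNNWNN", " " = "NWWNNNWNN", "*" = "NWNNWNWNN",
  "$" = "NWNWNWNNN", "/" = "NWNWNNNWN", "+" = "NWNNNWNWN", "%" = "NNNWNWNWN"
)

# mod-43 check values: the index of each character in this string
CODE39_CHECK_ALPHABET <- "0123456789ABCDEFGHIJKLMNOPQRSTUVWXYZ-. $/+%"

# wide elements span this many narrow modules in rendered output
CODE39_WIDE_RATIO <- 3L
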