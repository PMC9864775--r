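# Classic marching-cubes lookup table for binary indicator fields.
#
# Corner id of a unit cell = x + 2*y + 4*z (x, y, z in {0, 1}); edge ids
# 0..11 index MC_EDGE_MID, the edge midpoints in cell coordinates (for a
# binary field thresholded at 0.5 every surface vertex sits at an edge
# midpoint). MC_TRI holds one row per triangle: corner-pattern id (0..255)
# followed by the three edge ids, consistently oriented.

MC_EDGE_MID <- matrix(c(
  0.5, 0.0, 0.0,
  0.0, 0.5, 0.0,
  0.0, 0.0, 0.5,
  1.0, 0.5, 0.0,
  1.0, 0.0, 0.5,
  0.5, 1.0, 0.0,
  0.0, 1.0, 0.5,
  1.0, 1.0, 0.5,
  0.5, 0.0, 1.0,
  0.0, 0.5, 1.0,
  1.0, 0.5, 1.0,
  0.5, 1.0, 1.0
), ncol = 3, byrow = TRUE)

MC_TRI <- matrix(c(
  1, 1, 0, 2, 2, 0, 3, 4, 3, 2, 1, 4, 3, 4, 1, 3, 4, 6, 5, 1, 5, 6, 5, 2,
  5, 2, 5, 0, 6, 3, 4, 0, 6, 6, 5, 1, 7, 3, 4, 5, 7, 4, 6, 5, 7, 4, 2, 6,
  8, 5, 7, 3, 9, 0, 2, 1, 9, 7, 3, 5, 10, 4, 0, 7, 10, 7, 0, 5, 11, 5, 7, 1,
  11, 7, 2, 1, 11, 7, 4, 2, 12, 1, 6, 3, 12, 3, 6, 7, 13, 0, 2, 3,
  13, 2, 7, 3, 13, 2, 6, 7, 14, 1, 6, 0, 14, 6, 4, 0, 14, 6, 7, 4,
  15, 6, 4, 2, 15, 6, 7, 4, 16, 8, 9, 2, 17, 1, 0, 9, 17, 9, 0, 8,
  18, 8, 9, 2, 18, 3, 4, 0, 19, 8, 9, 4, 19, 9, 3, 4, 19, 9, 1, 3,
  20, 2, 8, 9, 20, 5, 1, 6, 21, 6, 5, 9, 21, 5, 8, 9, 21, 5, 0, 8,
  22, 9, 2, 8, 22, 3, 4, 0, 22, 5, 1, 6, 23, 5, 3, 4, 23, 5, 4, 8,
  23, 6, 5, 8, 23, 9, 6, 8, 24, 8, 9, 2, 24, 7, 3, 5, 25, 8, 9, 0,
  25, 9, 1, 0, 25, 7, 3, 5, 26, 5, 7, 0, 26, 7, 4, 0, 26, 9, 2, 8,
  27, 7, 4, 8, 27, 1, 7, 8, 27, 9, 1, 8, 27, 7, 1, 5, 28, 7, 3, 6,
  28, 3, 1, 6, 28, 8, 9, 2, 29, 6, 7, 9, 29, 7, 0, 9, 29, 0, 8, 9,
  29, 7, 3, 0, 30, 2, 8, 9, 30, 4, 1, 6, 30, 7, 4, 6, 30, 0, 1, 4,
  31, 4, 8, 9, 31, 6, 4, 9, 31, 7, 4, 6, 32, 4, 10, 8, 33, 4, 10, 8,
  33, 1, 0, 2, 34, 0, 3, 8, 34, 8, 3, 10, 35, 2, 1, 8, 35, 1, 10, 8,
  35, 1, 3, 10, 36, 4, 10, 8, 36, 5, 1, 6, 37, 6, 5, 2, 37, 5, 0, 2,
  37, 10, 8, 4, 38, 10, 8, 3, 38, 8, 0, 3, 38, 6, 5, 1, 39, 3, 10, 8,
  39, 6, 3, 8, 39, 2, 6, 8, 39, 5, 3, 6, 40, 10, 8, 4, 40, 5, 7, 3,
  41, 1, 0, 2, 41, 10, 8, 4, 41, 7, 3, 5, 42, 10, 8, 7, 42, 8, 5, 7,
  42, 8, 0, 5, 43, 5, 7, 1, 43, 1, 7, 2, 43, 7, 10, 2, 43, 10, 8, 2,
  44, 1, 6, 3, 44, 6, 7, 3, 44, 8, 4, 10, 45, 4, 10, 8, 45, 7, 0, 2,
  45, 6, 7, 2, 45, 3, 0, 7, 46, 8, 0, 10, 46, 0, 6, 10, 46, 6, 7, 10,
  46, 6, 0, 1, 47, 7, 10, 8, 47, 2, 7, 8, 47, 6, 7, 2, 48, 4, 10, 2,
  48, 2, 10, 9, 49, 4, 10, 0, 49, 10, 1, 0, 49, 10, 9, 1, 50, 0, 3, 2,
  50, 3, 9, 2, 50, 3, 10, 9, 51, 1, 10, 9, 51, 3, 10, 1, 52, 4, 10, 2,
  52, 10, 9, 2, 52, 5, 1, 6, 53, 10, 9, 6, 53, 0, 10, 6, 53, 5, 0, 6,
  53, 10, 0, 4, 54, 5, 1, 6, 54, 0, 9, 2, 54, 0, 3, 9, 54, 3, 10, 9,
  55, 9, 6, 5, 55, 3, 9, 5, 55, 10, 9, 3, 56, 9, 2, 10, 56, 2, 4, 10,
  56, 5, 7, 3, 57, 7, 3, 5, 57, 4, 1, 0, 57, 4, 10, 1, 57, 10, 9, 1,
  58, 0, 5, 2, 58, 5, 10, 2, 58, 10, 9, 2, 58, 5, 7, 10, 59, 1, 5, 7,
  59, 10, 1, 7, 59, 9, 1, 10, 60, 6, 7, 1, 60, 7, 3, 1, 60, 2, 10, 9,
  60, 2, 4, 10, 61, 0, 6, 7, 61, 3, 0, 7, 61, 0, 9, 6, 61, 10, 0, 4,
  61, 0, 10, 9, 62, 0, 10, 9, 62, 2, 0, 9, 62, 0, 7, 10, 62, 6, 0, 1,
  62, 0, 6, 7, 63, 7, 10, 9, 63, 7, 9, 6, 64, 11, 6, 9, 65, 1, 0, 2,
  65, 11, 6, 9, 66, 11, 6, 9, 66, 3, 4, 0, 67, 3, 4, 1, 67, 4, 2, 1,
  67, 11, 6, 9, 68, 9, 11, 1, 68, 1, 11, 5, 69, 9, 11, 2, 69, 11, 0, 2,
  69, 11, 5, 0, 70, 9, 11, 1, 70, 11, 5, 1, 70, 4, 0, 3, 71, 11, 5, 9,
  71, 5, 4, 9, 71, 4, 2, 9, 71, 4, 5, 3, 72, 6, 9, 11, 72, 3, 5, 7,
  73, 11, 6, 9, 73, 0, 2, 1, 73, 3, 5, 7, 74, 4, 0, 7, 74, 0, 5, 7,
  74, 9, 11, 6, 75, 11, 6, 9, 75, 5, 2, 1, 75, 5, 7, 2, 75, 7, 4, 2,
  76, 7, 3, 11, 76, 3, 9, 11, 76, 3, 1, 9, 77, 7, 3, 11, 77, 11, 3, 9,
  77, 3, 0, 9, 77, 0, 2, 9, 78, 1, 9, 0, 78, 9, 7, 0, 78, 7, 4, 0,
  78, 9, 11, 7, 79, 2, 9, 11, 79, 7, 2, 11, 79, 4, 2, 7, 80, 11, 6, 8,
  80, 8, 6, 2, 81, 1, 0, 6, 81, 0, 11, 6, 81, 0, 8, 11, 82, 11, 6, 8,
  82, 6, 2, 8, 82, 3, 4, 0, 83, 8, 11, 6, 83, 3, 8, 6, 83, 1, 3, 6,
  83, 4, 8, 3, 84, 2, 8, 1, 84, 8, 5, 1, 84, 8, 11, 5, 85, 11, 0, 8,
  85, 5, 0, 11, 86, 0, 3, 4, 86, 5, 2, 8, 86, 11, 5, 8, 86, 1, 2, 5,
  87, 5, 3, 4, 87, 8, 5, 4, 87, 11, 5, 8, 88, 2, 8, 6, 88, 8, 11, 6,
  88, 3, 5, 7, 89, 3, 5, 7, 89, 1, 11, 6, 89, 1, 0, 11, 89, 0, 8, 11,
  90, 0, 5, 4, 90, 5, 7, 4, 90, 8, 6, 2, 90, 8, 11, 6, 91, 1, 8, 11,
  91, 6, 1, 11, 91, 1, 4, 8, 91, 7, 1, 5, 91, 1, 7, 4, 92, 3, 1, 2,
  92, 11, 3, 2, 92, 8, 11, 2, 92, 3, 11, 7, 93, 11, 7, 3, 93, 0, 11, 3,
  93, 8, 11, 0, 94, 1, 7, 4, 94, 0, 1, 4, 94, 1, 11, 7, 94, 8, 1, 2,
  94, 1, 8, 11, 95, 4, 8, 11, 95, 4, 11, 7, 96, 11, 6, 9, 96, 4, 10, 8,
  97, 0, 2, 1, 97, 11, 6, 9, 97, 10, 8, 4, 98, 0, 3, 8, 98, 3, 10, 8,
  98, 6, 9, 11, 99, 6, 9, 11, 99, 2, 10, 8, 99, 2, 1, 10, 99, 1, 3, 10,
  100, 5, 1, 11, 100, 1, 9, 11, 100, 4, 10, 8, 101, 10, 8, 4, 101, 9, 0, 2,
  101, 9, 11, 0, 101, 11, 5, 0, 102, 0, 10, 8, 102, 3, 10, 0, 102, 1, 9, 11,
  102, 5, 1, 11, 103, 2, 3, 10, 103, 8, 2, 10, 103, 2, 5, 3, 103, 11, 2, 9,
  103, 2, 11, 5, 104, 4, 10, 8, 104, 6, 9, 11, 104, 5, 7, 3, 105, 3, 5, 7,
  105, 11, 6, 9, 105, 1, 0, 2, 105, 10, 8, 4, 106, 11, 6, 9, 106, 5, 10, 8,
  106, 0, 5, 8, 106, 7, 10, 5, 107, 1, 5, 2, 107, 5, 7, 2, 107, 7, 8, 2,
  107, 8, 7, 10, 107, 11, 6, 9, 108, 4, 10, 8, 108, 7, 9, 11, 108, 7, 3, 9,
  108, 3, 1, 9, 109, 11, 7, 9, 109, 7, 3, 9, 109, 3, 2, 9, 109, 2, 3, 0,
  109, 4, 10, 8, 110, 7, 1, 9, 110, 11, 7, 9, 110, 7, 0, 1, 110, 8, 7, 10,
  110, 7, 8, 0, 111, 2, 9, 11, 111, 7, 2, 11, 111, 2, 10, 8, 111, 2, 7, 10,
  112, 11, 6, 10, 112, 6, 4, 10, 112, 6, 2, 4, 113, 10, 11, 6, 113, 10, 6, 1,
  113, 4, 10, 1, 113, 0, 4, 1, 114, 6, 2, 0, 114, 10, 6, 0, 114, 3, 10, 0,
  114, 6, 10, 11, 115, 10, 11, 6, 115, 1, 10, 6, 115, 3, 10, 1,
  116, 2, 4, 10, 116, 5, 2, 10, 116, 11, 5, 10, 116, 1, 2, 5, 117, 0, 4, 10,
  117, 11, 0, 10, 117, 5, 0, 11, 118, 2, 11, 5, 118, 1, 2, 5, 118, 2, 10, 11,
  118, 3, 2, 0, 118, 2, 3, 10, 119, 10, 11, 5, 119, 10, 5, 3, 120, 5, 7, 3,
  120, 11, 4, 10, 120, 11, 6, 4, 120, 6, 2, 4, 121, 0, 4, 1, 121, 4, 10, 1,
  121, 10, 6, 1, 121, 6, 10, 11, 121, 7, 3, 5, 122, 10, 0, 5, 122, 7, 10, 5,
  122, 10, 2, 0, 122, 6, 10, 11, 122, 10, 6, 2, 123, 1, 5, 7, 123, 10, 1, 7,
  123, 1, 11, 6, 123, 1, 10, 11, 124, 11, 2, 4, 124, 10, 11, 4,
  124, 11, 1, 2, 124, 3, 11, 7, 124, 11, 3, 1, 125, 11, 7, 3, 125, 0, 11, 3,
  125, 11, 4, 10, 125, 11, 0, 4, 126, 0, 1, 2, 126, 11, 7, 10,
  127, 7, 10, 11, 128, 10, 7, 11, 129, 1, 0, 2, 129, 7, 11, 10,
  130, 7, 11, 10, 130, 0, 3, 4, 131, 2, 1, 4, 131, 1, 3, 4, 131, 11, 10, 7,
  132, 5, 1, 6, 132, 10, 7, 11, 133, 0, 2, 5, 133, 2, 6, 5, 133, 10, 7, 11,
  134, 6, 5, 1, 134, 4, 0, 3, 134, 10, 7, 11, 135, 7, 11, 10, 135, 6, 3, 4,
  135, 2, 6, 4, 135, 5, 3, 6, 136, 11, 10, 5, 136, 5, 10, 3, 137, 11, 10, 5,
  137, 10, 3, 5, 137, 2, 1, 0, 138, 4, 0, 10, 138, 0, 11, 10, 138, 0, 5, 11,
  139, 4, 2, 10, 139, 2, 5, 10, 139, 5, 11, 10, 139, 2, 1, 5, 140, 11, 10, 6,
  140, 10, 1, 6, 140, 10, 3, 1, 141, 2, 6, 0, 141, 6, 10, 0, 141, 10, 3, 0,
  141, 10, 6, 11, 142, 11, 10, 6, 142, 6, 10, 1, 142, 10, 4, 1, 142, 4, 0, 1,
  143, 6, 11, 10, 143, 4, 6, 10, 143, 2, 6, 4, 144, 9, 2, 8, 144, 7, 11, 10,
  145, 1, 0, 9, 145, 0, 8, 9, 145, 7, 11, 10, 146, 2, 8, 9, 146, 7, 11, 10,
  146, 3, 4, 0, 147, 10, 7, 11, 147, 3, 8, 9, 147, 1, 3, 9, 147, 4, 8, 3,
  148, 8, 9, 2, 148, 5, 1, 6, 148, 7, 11, 10, 149, 7, 11, 10, 149, 6, 8, 9,
  149, 6, 5, 8, 149, 5, 0, 8, 150, 8, 9, 2, 150, 0, 3, 4, 150, 5, 1, 6,
  150, 7, 11, 10, 151, 9, 6, 8, 151, 6, 5, 8, 151, 5, 4, 8, 151, 4, 5, 3,
  151, 7, 11, 10, 152, 3, 5, 10, 152, 5, 11, 10, 152, 2, 8, 9,
  153, 10, 3, 11, 153, 3, 5, 11, 153, 9, 0, 8, 153, 9, 1, 0, 154, 8, 9, 2,
  154, 11, 4, 0, 154, 5, 11, 0, 154, 10, 4, 11, 155, 4, 5, 11,
  155, 10, 4, 11, 155, 4, 1, 5, 155, 9, 4, 8, 155, 4, 9, 1, 156, 9, 2, 8,
  156, 1, 11, 10, 156, 3, 1, 10, 156, 6, 11, 1, 157, 6, 0, 8, 157, 9, 6, 8,
  157, 6, 3, 0, 157, 10, 6, 11, 157, 6, 10, 3, 158, 6, 11, 1, 158, 11, 10, 1,
  158, 10, 0, 1, 158, 0, 10, 4, 158, 8, 9, 2, 159, 6, 11, 10, 159, 4, 6, 10,
  159, 6, 8, 9, 159, 6, 4, 8, 160, 8, 4, 11, 160, 11, 4, 7, 161, 7, 11, 4,
  161, 11, 8, 4, 161, 1, 0, 2, 162, 7, 11, 3, 162, 11, 0, 3, 162, 11, 8, 0,
  163, 1, 3, 2, 163, 3, 11, 2, 163, 11, 8, 2, 163, 11, 3, 7, 164, 8, 4, 11,
  164, 4, 7, 11, 164, 1, 6, 5, 165, 6, 0, 2, 165, 5, 0, 6, 165, 11, 8, 4,
  165, 7, 11, 4, 166, 5, 1, 6, 166, 0, 7, 11, 166, 8, 0, 11, 166, 3, 7, 0,
  167, 3, 2, 6, 167, 5, 3, 6, 167, 3, 8, 2, 167, 11, 3, 7, 167, 3, 11, 8,
  168, 3, 5, 4, 168, 5, 8, 4, 168, 5, 11, 8, 169, 1, 0, 2, 169, 3, 8, 4,
  169, 3, 5, 8, 169, 5, 11, 8, 170, 0, 11, 8, 170, 0, 5, 11, 171, 8, 2, 1,
  171, 5, 8, 1, 171, 11, 8, 5, 172, 11, 8, 6, 172, 8, 3, 6, 172, 3, 1, 6,
  172, 8, 4, 3, 173, 3, 11, 8, 173, 4, 3, 8, 173, 3, 6, 11, 173, 2, 3, 0,
  173, 3, 2, 6, 174, 0, 1, 6, 174, 11, 0, 6, 174, 8, 0, 11, 175, 6, 11, 8,
  175, 6, 8, 2, 176, 9, 2, 11, 176, 2, 7, 11, 176, 2, 4, 7, 177, 9, 1, 0,
  177, 7, 9, 0, 177, 4, 7, 0, 177, 11, 9, 7, 178, 3, 7, 11, 178, 3, 11, 9,
  178, 0, 3, 9, 178, 2, 0, 9, 179, 3, 7, 11, 179, 9, 3, 11, 179, 1, 3, 9,
  180, 6, 5, 1, 180, 7, 9, 2, 180, 4, 7, 2, 180, 11, 9, 7, 181, 9, 4, 7,
  181, 11, 9, 7, 181, 9, 0, 4, 181, 5, 9, 6, 181, 9, 5, 0, 182, 2, 0, 9,
  182, 0, 3, 9, 182, 3, 11, 9, 182, 11, 3, 7, 182, 5, 1, 6, 183, 9, 6, 5,
  183, 3, 9, 5, 183, 9, 7, 11, 183, 9, 3, 7, 184, 5, 11, 9, 184, 4, 5, 9,
  184, 2, 4, 9, 184, 5, 4, 3, 185, 4, 9, 1, 185, 0, 4, 1, 185, 4, 11, 9,
  185, 5, 4, 3, 185, 4, 5, 11, 186, 11, 9, 2, 186, 0, 11, 2, 186, 5, 11, 0,
  187, 11, 9, 1, 187, 11, 1, 5, 188, 11, 3, 1, 188, 6, 11, 1, 188, 11, 4, 3,
  188, 2, 11, 9, 188, 11, 2, 4, 189, 6, 11, 9, 189, 4, 3, 0, 190, 0, 1, 6,
  190, 11, 0, 6, 190, 0, 9, 2, 190, 0, 11, 9, 191, 6, 11, 9, 192, 10, 7, 9,
  192, 9, 7, 6, 193, 10, 7, 9, 193, 7, 6, 9, 193, 0, 2, 1, 194, 6, 9, 7,
  194, 9, 10, 7, 194, 0, 3, 4, 195, 10, 6, 9, 195, 7, 6, 10, 195, 4, 2, 1,
  195, 3, 4, 1, 196, 5, 1, 7, 196, 1, 10, 7, 196, 1, 9, 10, 197, 5, 0, 2,
  197, 10, 5, 2, 197, 9, 10, 2, 197, 7, 5, 10, 198, 3, 4, 0, 198, 10, 5, 1,
  198, 9, 10, 1, 198, 7, 5, 10, 199, 5, 9, 10, 199, 7, 5, 10, 199, 5, 2, 9,
  199, 4, 5, 3, 199, 5, 4, 2, 200, 6, 9, 5, 200, 9, 3, 5, 200, 9, 10, 3,
  201, 1, 0, 2, 201, 3, 6, 9, 201, 10, 3, 9, 201, 5, 6, 3, 202, 9, 10, 6,
  202, 10, 0, 6, 202, 0, 5, 6, 202, 0, 10, 4, 203, 5, 4, 2, 203, 1, 5, 2,
  203, 5, 10, 4, 203, 9, 5, 6, 203, 5, 9, 10, 204, 10, 1, 9, 204, 10, 3, 1,
  205, 3, 0, 2, 205, 9, 3, 2, 205, 10, 3, 9, 206, 10, 4, 0, 206, 1, 10, 0,
  206, 9, 10, 1, 207, 10, 4, 2, 207, 10, 2, 9, 208, 10, 7, 8, 208, 7, 2, 8,
  208, 7, 6, 2, 209, 0, 8, 10, 209, 6, 0, 10, 209, 7, 6, 10, 209, 0, 6, 1,
  210, 3, 4, 0, 210, 10, 2, 8, 210, 10, 7, 2, 210, 7, 6, 2, 211, 8, 1, 3,
  211, 4, 8, 3, 211, 8, 6, 1, 211, 7, 8, 10, 211, 8, 7, 6, 212, 7, 5, 1,
  212, 7, 1, 2, 212, 10, 7, 2, 212, 8, 10, 2, 213, 8, 10, 7, 213, 5, 8, 7,
  213, 0, 8, 5, 214, 8, 10, 2, 214, 10, 7, 2, 214, 7, 1, 2, 214, 1, 7, 5,
  214, 3, 4, 0, 215, 8, 10, 7, 215, 5, 8, 7, 215, 8, 3, 4, 215, 8, 5, 3,
  216, 10, 3, 8, 216, 3, 6, 8, 216, 6, 2, 8, 216, 3, 5, 6, 217, 6, 10, 3,
  217, 5, 6, 3, 217, 6, 8, 10, 217, 0, 6, 1, 217, 6, 0, 8, 218, 10, 6, 2,
  218, 8, 10, 2, 218, 10, 5, 6, 218, 0, 10, 4, 218, 10, 0, 5, 219, 10, 4, 8,
  219, 1, 5, 6, 220, 1, 2, 8, 220, 10, 1, 8, 220, 3, 1, 10, 221, 3, 0, 8,
  221, 3, 8, 10, 222, 10, 4, 0, 222, 1, 10, 0, 222, 10, 2, 8, 222, 10, 1, 2,
  223, 10, 4, 8, 224, 8, 4, 9, 224, 4, 6, 9, 224, 4, 7, 6, 225, 0, 2, 1,
  225, 8, 6, 9, 225, 8, 4, 6, 225, 4, 7, 6, 226, 7, 6, 9, 226, 0, 7, 9,
  226, 8, 0, 9, 226, 3, 7, 0, 227, 8, 7, 6, 227, 9, 8, 6, 227, 8, 3, 7,
  227, 1, 8, 2, 227, 8, 1, 3, 228, 4, 7, 8, 228, 7, 1, 8, 228, 1, 9, 8,
  228, 1, 7, 5, 229, 9, 5, 0, 229, 2, 9, 0, 229, 9, 7, 5, 229, 4, 9, 8,
  229, 9, 4, 7, 230, 7, 8, 0, 230, 3, 7, 0, 230, 7, 9, 8, 230, 1, 7, 5,
  230, 7, 1, 9, 231, 9, 8, 2, 231, 3, 7, 5, 232, 3, 5, 4, 232, 4, 5, 8,
  232, 5, 6, 8, 232, 6, 9, 8, 233, 4, 3, 8, 233, 3, 5, 8, 233, 5, 9, 8,
  233, 9, 5, 6, 233, 1, 0, 2, 234, 5, 6, 9, 234, 8, 5, 9, 234, 0, 5, 8,
  235, 8, 2, 1, 235, 5, 8, 1, 235, 8, 6, 9, 235, 8, 5, 6, 236, 9, 8, 4,
  236, 3, 9, 4, 236, 1, 9, 3, 237, 9, 8, 4, 237, 3, 9, 4, 237, 9, 0, 2,
  237, 9, 3, 0, 238, 0, 1, 9, 238, 0, 9, 8, 239, 9, 8, 2, 240, 4, 6, 2,
  240, 7, 6, 4, 241, 6, 1, 0, 241, 4, 6, 0, 241, 7, 6, 4, 242, 2, 0, 3,
  242, 7, 2, 3, 242, 6, 2, 7, 243, 6, 1, 3, 243, 6, 3, 7, 244, 7, 5, 1,
  244, 2, 7, 1, 244, 4, 7, 2, 245, 0, 4, 7, 245, 0, 7, 5, 246, 2, 0, 3,
  246, 7, 2, 3, 246, 2, 5, 1, 246, 2, 7, 5, 247, 7, 5, 3, 248, 4, 3, 5,
  248, 6, 4, 5, 248, 2, 4, 6, 249, 4, 3, 5, 249, 6, 4, 5, 249, 4, 1, 0,
  249, 4, 6, 1, 250, 5, 6, 2, 250, 5, 2, 0, 251, 5, 6, 1, 252, 1, 2, 4,
  252, 1, 4, 3, 253, 3, 0, 4, 254, 0, 1, 2
), ncol = 4, byrow = TRUE)

# 0-based corner ids (a, b) of each edge
MC_EDGE_CORNERS <- matrix(c(
  0, 1,
  0, 2,
  0, 4,
  1, 3,
  1, 5,
  2, 3,
  2, 6,
  3, 7,
  4, 5,
  4, 6,
  5, 7,
  6, 7
), ncol = 2, byrow = TRUE)
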