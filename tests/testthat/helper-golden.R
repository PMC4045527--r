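# Golden per-examination risk table: printed dose endpoints (mGy) and the
# "1 in N" denominators of the childhood-cancer and hereditary risk columns.
# NA marks cells excluded because the printed risk is inconsistent with the
# printed dose endpoint under the table's own rounding convention (the
# AP-chest upper cells correspond to a dose of 0.01, not the printed 0.001).
golden_risk_table <- function() {
  tibble::tribble(
    ~exam,                 ~dose_lo, ~dose_hi, ~cancer_lo, ~cancer_hi, ~hered_lo, ~hered_hi,
    "AP Abdomen",              0.05,     3.74,     250000,       3300,   3300000,     50000,
    "AP Chest",               0.001,    0.001,   12500000,         NA, 200000000,        NA,
    "LAT Chest",              0.001,     0.01,   12500000,    1250000, 200000000,  20000000,
    "PA Chest",               0.001,     0.01,   12500000,    1250000, 200000000,  20000000,
    "PA Colon",                1.66,     2.20,      10000,       5000,    125000,    100000,
    "Hip joint",               0.01,     0.05,    1250000,     250000,  20000000,   3300000,
    "AP Lumbar spine",         0.11,     4.42,     110000,       2500,   1700000,     50000,
    "PA Lumbar spine",         0.02,     0.80,     500000,      17000,  10000000,    250000,
    "LAT Lumbar spine",        0.03,     3.89,     500000,       3300,   5000000,     50000,
    "Lumbosacral joint",       0.02,     0.80,     500000,      17000,  10000000,    250000,
    "AP Pelvis",               0.18,     1.07,     100000,      11000,   1100000,    200000,
    "AP Stomach",              0.01,     1.33,    1250000,      10000,  20000000,    140000,
    "LAO Stomach",             0.01,     0.01,    1250000,    1250000,  20000000,  20000000,
    "LAT Stomach",             0.01,     0.01,    1250000,    1250000,  20000000,  20000000,
    "LPO Stomach",             0.01,     0.01,    1250000,    1250000,  20000000,  20000000,
    "PA Stomach",              0.01,     0.01,    1250000,    1250000,  20000000,  20000000,
    "AP Thoracic spine",      0.001,     0.85,   12500000,      14000, 200000000,    250000,
    "LAT Thoracic spine",     0.001,    0.001,   12500000,   12500000, 200000000, 200000000,
    "Barium enema",            1.14,    16.27,      11000,       1000,    170000,     12500,
    "Barium meal",             0.08,     0.19,     170000,      50000,   2500000,   1000000,
    "Cholangiography",         1.57,     6.65,      10000,       2000,    125000,     33000,
    "Barium follow through",   0.17,     0.64,     100000,      20000,   1100000,    330000,
    "IVU",                     0.05,     1.33,     250000,      10000,   3300000,    140000,
    "KUB",                     0.01,     0.59,    1250000,      20000,  20000000,    330000,
    "AP Urinary bladder",      1.49,     1.49,      10000,      10000,    140000,    140000,
    "Nephrostomy",             0.01,     0.37,    1250000,      33000,  20000000,    500000,
    "CT-Abdomen",              1.04,     3.65,      12500,       3300,    200000,     50000,
    "CT-Chest",                0.02,     0.02,     500000,     500000,  10000000,  10000000,
    "CT-Lumbar spine",        13.61,    21.85,       1000,        500,     14000,     10000,
    "CT-Pelvis",               1.32,    17.06,      10000,       1000,    140000,     11000
  )
}

# Rows whose printed range strings are typographically clean, with the
# strings exactly as printed (en dash, no stray spaces, no "<" carry-over).
golden_risk_strings <- function() {
  tibble::tribble(
    ~exam,                 ~dose_lo, ~dose_hi, ~cancer_string,               ~hered_string,
    "AP Abdomen",              0.05,     3.74, "1 in 250000–1 in 3300",      "1 in 3300000–1 in 50000",
    "PA Colon",                1.66,     2.20, "1 in 10000–1 in 5000",       "1 in 125000–1 in 100000",
    "AP Lumbar spine",         0.11,     4.42, "1 in 110000–1 in 2500",      "1 in 1700000–1 in 50000",
    "PA Lumbar spine",         0.02,     0.80, "1 in 500000–1 in 17000",     "1 in 10000000–1 in 250000",
    "LAT Lumbar spine",        0.03,     3.89, "1 in 500000–1 in 3300",      "1 in 5000000–1 in 50000",
    "AP Pelvis",               0.18,     1.07, "1 in 100000–1 in 11000",     "1 in 1100000–1 in 200000",
    "AP Stomach",              0.01,     1.33, "1 in 1250000–1 in 10000",    "1 in 20000000–1 in 140000",
    "Barium enema",            1.14,    16.27, "1 in 11000–1 in 1000",       "1 in 170000–1 in 12500",
    "Barium meal",             0.08,     0.19, "1 in 170000–1 in 50000",     "1 in 2500000–1 in 1000000",
    "Cholangiography",         1.57,     6.65, "1 in 10000–1 in 2000",       "1 in 125000–1 in 33000",
    "Barium follow through",   0.17,     0.64, "1 in 100000–1 in 20000",     "1 in 1100000–1 in 330000",
    "IVU",                     0.05,     1.33, "1 in 250000–1 in 10000",     "1 in 3300000–1 in 140000",
    "CT-Abdomen",              1.04,     3.65, "1 in 12500–1 in 3300",       "1 in 200000–1 in 50000",
    "CT-Lumbar spine",        13.61,    21.85, "1 in 1000–1 in 500",         "1 in 14000–1 in 10000",
    "CT-Pelvis",               1.32,    17.06, "1 in 10000–1 in 1000",       "1 in 140000–1 in 11000"
  )
}
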