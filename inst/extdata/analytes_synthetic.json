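{
  "__comment": "Synthetic evaluation fixtures: six analyte mixture designs constructed from each analyte's typical reference-interval scale and skewness class. Non-pathological component: Box-Cox normal with the given lambda whose 2.5th/97.5th percentiles equal ri_lower/ri_upper. te_percent: classic desirable total-error specification (biological-variation database tier), converted to measurement units at the reference-interval midpoint. cells: [left_fraction, right_fraction] pathological admixture; the left range spans (0.51, 1.02) x ri_lower, the right range (0.96, 1.73) x ri_upper. These are package-designed synthetic conditions, not transcriptions of any external dataset.",
  "ALP": {
    "label": "ALP", "unit": "U/L", "lam": 0.3,
    "ri_lower": 115, "ri_upper": 360, "te_percent": 12.04, "n": 10000,
    "cells": [[0, 0], [0.10, 0.05], [0.15, 0.20], [0.20, 0.10], [0.30, 0.30]]
  },
  "CREA": {
    "label": "CREA", "unit": "umol/L", "lam": 0.6,
    "ri_lower": 49, "ri_upper": 73, "te_percent": 8.87, "n": 10000,
    "cells": [[0, 0], [0.10, 0.05], [0.15, 0.20], [0.20, 0.10], [0.30, 0.30]]
  },
  "Hb": {
    "label": "Hb", "unit": "g/dL", "lam": 1.0,
    "ri_lower": 12, "ri_upper": 16, "te_percent": 4.14, "n": 10000,
    "cells": [[0, 0], [0.10, 0.05], [0.15, 0.20], [0.20, 0.10], [0.30, 0.30]]
  },
  "FT4": {
    "label": "FT4", "unit": "pmol/L", "lam": 0.8,
    "ri_lower": 12, "ri_upper": 22, "te_percent": 8.0, "n": 10000,
    "cells": [[0, 0], [0.10, 0.05], [0.15, 0.20], [0.20, 0.10], [0.30, 0.30]]
  },
  "TSH": {
    "label": "TSH", "unit": "mIU/L", "lam": 0.0,
    "ri_lower": 0.5, "ri_upper": 4.0, "te_percent": 23.7, "n": 10000,
    "cells": [[0, 0], [0, 0.10], [0, 0.20], [0, 0.30], [0.10, 0.20]]
  },
  "GGT": {
    "label": "GGT", "unit": "U/L", "lam": 0.1,
    "ri_lower": 9, "ri_upper": 40, "te_percent": 22.11, "n": 10000,
    "cells": [[0, 0], [0, 0.10], [0, 0.20], [0, 0.30], [0.10, 0.20]]
  }
}
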