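#!/usr/bin/env python
"""Reference SSIM (Wang et al. variant) via scikit-image."""
import sys

import numpy as np
from skimage.metrics import structural_similarity

a = np.loadtxt(sys.argv[1])
b = np.loadtxt(sys.argv[2])
val = structural_similarity(
    a, b, data_range=float(sys.argv[3]), gaussian_weights=True, sigma=1.5,
    use_sample_covariance=False)
print(float(val))
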