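#!/usr/bin/env python
"""Reference pixel-domain multi-scale visual information fidelity.

Independent implementation of the classic VIFP algorithm built on
scipy.ndimage primitives (4 dyadic scales, Gaussian windows of size
2^(5-s)+1 with sd N/5, HVS noise variance 2).
"""
import sys

import numpy as np
from scipy.ndimage import correlate


def gauss_window(N):
    s = N / 5.0
    x = np.arange(N) - (N - 1) / 2.0
    k = np.exp(-0.5 * (x / s) ** 2)
    k /= k.sum()
    return np.outer(k, k)


def valid(img, win):
    N = win.shape[0]
    r = (N - 1) // 2
    out = correlate(img, win, mode="constant")
    return out[r:img.shape[0] - r, r:img.shape[1] - r]


def vifp(ref, dist, sigma_nsq=2.0):
    eps = 1e-10
    num = den = 0.0
    for scale in range(1, 5):
        N = 2 ** (4 - scale + 1) + 1
        win = gauss_window(N)
        if scale > 1:
            ref = valid(ref, win)[::2, ::2]
            dist = valid(dist, win)[::2, ::2]
        mu1, mu2 = valid(ref, win), valid(dist, win)
        s1 = valid(ref * ref, win) - mu1 ** 2
        s2 = valid(dist * dist, win) - mu2 ** 2
        s12 = valid(ref * dist, win) - mu1 * mu2
        s1[s1 < 0] = 0
        s2[s2 < 0] = 0
        g = s12 / (s1 + eps)
        sv = s2 - g * s12
        g[s1 < eps] = 0
        sv[s1 < eps] = s2[s1 < eps]
        s1[s1 < eps] = 0
        g[s2 < eps] = 0
        sv[s2 < eps] = 0
        sv[g < 0] = s2[g < 0]
        g[g < 0] = 0
        sv[sv <= eps] = eps
        num += np.sum(np.log10(1 + g * g * s1 / (sv + sigma_nsq)))
        den += np.sum(np.log10(1 + s1 / sigma_nsq))
    return num / den


ref = np.loadtxt(sys.argv[1])
dist = np.loadtxt(sys.argv[2])
print(float(vifp(ref, dist)))
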