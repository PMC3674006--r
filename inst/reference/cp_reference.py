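"""Reference CP-ALS implementation used as an independent cross-check.

Plain dense (no missing data) rank-R CANDECOMP/PARAFAC by alternating
least squares with numpy's lstsq, multiple random starts.  Reads a job
file: line 1 "I J K R n_starts", then I*J*K tensor values in column-major
(Fortran) order.  Prints the relative fit 1 - ||X - Xhat||^2 / ||X||^2 of
the best start.

Usage: python cp_reference.py job1.txt [job2.txt ...]
"""
import sys

import numpy as np


def khatri_rao(U, V):
    R = U.shape[1]
    return np.einsum("ir,jr->ijr", U, V).reshape(-1, R)


def cp_als(X, rank, n_starts=5, max_iter=2000, tol=1e-12, seed=0):
    I, J, K = X.shape
    X1 = X.reshape(I, J * K, order="F")
    X2 = np.transpose(X, (1, 0, 2)).reshape(J, I * K, order="F")
    X3 = np.transpose(X, (2, 0, 1)).reshape(K, I * J, order="F")
    tss = (X ** 2).sum()
    rng = np.random.default_rng(seed)
    best = np.inf
    for s in range(n_starts):
        A = rng.standard_normal((I, rank))
        B = rng.standard_normal((J, rank))
        C = rng.standard_normal((K, rank))
        prev = np.inf
        for _ in range(max_iter):
            A = np.linalg.lstsq(khatri_rao(C, B), X1.T, rcond=None)[0].T
            B = np.linalg.lstsq(khatri_rao(C, A), X2.T, rcond=None)[0].T
            C = np.linalg.lstsq(khatri_rao(B, A), X3.T, rcond=None)[0].T
            rss = ((X1 - A @ khatri_rao(C, B).T) ** 2).sum()
            if prev - rss < tol * max(prev, 1e-300):
                break
            prev = rss
        best = min(best, rss)
    return 1.0 - best / tss


def main(paths):
    for path in paths:
        with open(path) as fh:
            header = fh.readline().split()
            I, J, K, R, n_starts = (int(v) for v in header)
            vals = np.loadtxt(fh)
        X = vals.reshape((I, J, K), order="F")
        print(f"{cp_als(X, R, n_starts=n_starts):.12f}")


if __name__ == "__main__":
    main(sys.argv[1:])
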