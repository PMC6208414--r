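#!/usr/bin/env python
"""Reference Markov clustering on a dense matrix.

Independent re-implementation of the MCL iteration used for
cross-validation of the package's sparse-matrix clustering: column
stochastic matrix with self-loops (loop weight = max incident edge weight,
1 for isolated nodes), expansion (matrix squaring), inflation (entrywise
power + column renormalization), pruning of entries below a floor with
renormalization, until the maximum entrywise change falls below a
tolerance. Clusters are the connected components of the nonzero structure
of the limit matrix (which merges overlapping attractor systems).

Usage:
    python mcl_reference.py EDGES.abc NODES.txt INFLATION MAX_ITER PRUNE TOL

EDGES.abc: three columns (node_a, node_b, weight), whitespace separated.
NODES.txt: one node id per line (fixes the universe incl. isolated nodes).
Output: one cluster per line, members tab-separated and sorted; clusters
sorted by their first member.
"""
import sys

import numpy as np


def main(argv):
    edges_path, nodes_path = argv[1], argv[2]
    inflation = float(argv[3])
    max_iter = int(argv[4])
    prune = float(argv[5])
    tol = float(argv[6])

    with open(nodes_path) as fh:
        nodes = [ln.strip() for ln in fh if ln.strip()]
    idx = {n: i for i, n in enumerate(nodes)}
    n = len(nodes)

    A = np.zeros((n, n))
    with open(edges_path) as fh:
        for ln in fh:
            parts = ln.split()
            if len(parts) < 3:
                continue
            i, j, w = idx[parts[0]], idx[parts[1]], float(parts[2])
            if i == j:
                continue
            A[i, j] = max(A[i, j], w)
            A[j, i] = A[i, j]

    loops = A.max(axis=0)
    loops[loops == 0] = 1.0
    A[np.diag_indices(n)] = loops

    M = A / A.sum(axis=0, keepdims=True)
    for _ in range(max_iter):
        prev = M
        M = M @ M
        M = M ** inflation
        M = M / M.sum(axis=0, keepdims=True)
        M[M < prune] = 0.0
        M = M / M.sum(axis=0, keepdims=True)
        if np.abs(M - prev).max() < tol:
            break

    # connected components of the nonzero structure (union-find)
    parent = list(range(n))

    def find(x):
        while parent[x] != x:
            parent[x] = parent[parent[x]]
            x = parent[x]
        return x

    def union(a, b):
        ra, rb = find(a), find(b)
        if ra != rb:
            parent[rb] = ra

    ii, jj = np.nonzero(M)
    for a, b in zip(ii, jj):
        union(int(a), int(b))

    clusters = {}
    for i, node in enumerate(nodes):
        clusters.setdefault(find(i), []).append(node)
    out = sorted((sorted(c) for c in clusters.values()), key=lambda c: c[0])
    for c in out:
        sys.stdout.write("\t".join(c) + "\n")


if __name__ == "__main__":
    main(sys.argv)
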