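"""Convert between an AnnData .h5ad file and the plain-text csv_mtx bundle
(matrix.mtx genes x spots, genes.tsv, barcodes.tsv, coords.csv, labels.tsv).

Usage: python h5ad_bridge.py {to_bundle|from_bundle} SRC DST
"""
import sys
import os

import numpy as np
import scipy.sparse as sp
import scipy.io as sio
import anndata as ad


def to_bundle(src, dst):
    a = ad.read_h5ad(src)
    if "spatial" not in a.obsm:
        sys.stderr.write("h5ad file has no obsm['spatial'] coordinate slot\n")
        sys.exit(3)
    os.makedirs(dst, exist_ok=True)
    x = a.X
    if not sp.issparse(x):
        x = sp.csr_matrix(np.asarray(x))
    sio.mmwrite(os.path.join(dst, "matrix.mtx"), x.T.tocoo())
    with open(os.path.join(dst, "genes.tsv"), "w") as f:
        f.write("\n".join(map(str, a.var_names)) + "\n")
    with open(os.path.join(dst, "barcodes.tsv"), "w") as f:
        f.write("\n".join(map(str, a.obs_names)) + "\n")
    co = np.asarray(a.obsm["spatial"], dtype=float)
    with open(os.path.join(dst, "coords.csv"), "w") as f:
        f.write("barcode,x,y\n")
        for b, (cx, cy) in zip(a.obs_names, co[:, :2]):
            f.write(f"{b},{float(cx)!r},{float(cy)!r}\n")
    if "domain" in a.obs:
        with open(os.path.join(dst, "labels.tsv"), "w") as f:
            f.write("barcode\tlabel\n")
            for b, lab in zip(a.obs_names, a.obs["domain"].astype(str)):
                f.write(f"{b}\t{lab}\n")


def from_bundle(src, dst):
    x = sio.mmread(os.path.join(src, "matrix.mtx")).tocsr().T.tocsr()
    genes = open(os.path.join(src, "genes.tsv")).read().split()
    barcodes = open(os.path.join(src, "barcodes.tsv")).read().split()
    coords = {}
    with open(os.path.join(src, "coords.csv")) as f:
        next(f)
        for line in f:
            b, cx, cy = line.rstrip("\n").split(",")
            coords[b] = (float(cx), float(cy))
    a = ad.AnnData(X=x)
    a.obs_names = barcodes
    a.var_names = genes
    a.obsm["spatial"] = np.array([coords[b] for b in barcodes])
    labf = os.path.join(src, "labels.tsv")
    if os.path.exists(labf):
        lab = {}
        with open(labf) as f:
            next(f)
            for line in f:
                b, l = line.rstrip("\n").split("\t")
                lab[b] = l
        a.obs["domain"] = [lab.get(b, "NA") for b in barcodes]
    a.write_h5ad(dst)


if __name__ == "__main__":
    if len(sys.argv) != 4 or sys.argv[1] not in ("to_bundle", "from_bundle"):
        sys.stderr.write(__doc__)
        sys.exit(2)
    {"to_bundle": to_bundle, "from_bundle": from_bundle}[sys.argv[1]](
        sys.argv[2], sys.argv[3])
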