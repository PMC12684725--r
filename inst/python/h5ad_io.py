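"""CSV <-> H5AD bridge used by tagtrace::write_outputs() and read_h5ad_counts().

write mode: h5ad_io.py write <counts.csv> <out.h5ad> <meta.json>
    meta.json: {"modality": ..., "params": {...}, "n_label_cols": 1 or 2}
read mode:  h5ad_io.py read <in.h5ad> <out.csv>
"""
import json
import sys

import anndata as ad
import numpy as np
import pandas as pd


def write(csv_path, h5_path, meta_path):
    with open(meta_path) as fh:
        meta = json.load(fh)
    nlab = int(meta.get("n_label_cols", 1))
    df = pd.read_csv(csv_path, dtype={i: str for i in range(nlab)})
    obs = df.iloc[:, :nlab].copy()
    obs.columns = ["sample_id"] if nlab == 1 else ["sample_id", "cell_barcode"]
    if nlab == 1:
        obs.index = obs["sample_id"].astype(str)
    else:
        obs.index = (obs["sample_id"].astype(str) + ","
                     + obs["cell_barcode"].astype(str))
    X = df.iloc[:, nlab:].to_numpy(dtype=np.int64)
    var = pd.DataFrame(index=df.columns[nlab:])
    adata = ad.AnnData(X=X, obs=obs, var=var)
    adata.uns["modality"] = meta.get("modality", "bulk")
    adata.uns["params"] = meta.get("params") or {}
    adata.write_h5ad(h5_path)


def read(h5_path, csv_path):
    adata = ad.read_h5ad(h5_path)
    X = np.asarray(adata.X)
    out = pd.concat(
        [adata.obs.reset_index(drop=True),
         pd.DataFrame(X, columns=list(adata.var_names))], axis=1)
    out.to_csv(csv_path, index=False)


if __name__ == "__main__":
    mode = sys.argv[1]
    if mode == "write":
        write(sys.argv[2], sys.argv[3], sys.argv[4])
    elif mode == "read":
        read(sys.argv[2], sys.argv[3])
    else:
        sys.exit("unknown mode: " + mode)
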