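"""Bridge: dump a FIF / CTF .ds recording to TSV + JSON for the R reader.

Usage: python export_recording.py <input> <fif|ctf_ds> <outdir>
Writes <outdir>/data.tsv (channels x samples, one channel per line) and
<outdir>/meta.json {rate, channel_names, channel_roles}.
"""
import json
import os
import sys

import mne
import numpy as np

ROLE_MAP = {
    "grad": "meg_gradiometer",
    "mag": "meg_gradiometer",
    "ref_meg": "reference",
    "ecg": "ecg_bipolar",
}


def main(path, fmt, outdir):
    if fmt == "fif":
        raw = mne.io.read_raw_fif(path, preload=True, verbose="error")
    elif fmt == "ctf_ds":
        raw = mne.io.read_raw_ctf(path, preload=True, verbose="error")
    else:
        raise SystemExit(f"unknown format: {fmt}")
    data = raw.get_data()
    types = raw.get_channel_types()
    roles = [ROLE_MAP.get(t, "other") for t in types]
    np.savetxt(os.path.join(outdir, "data.tsv"), data, delimiter="\t")
    with open(os.path.join(outdir, "meta.json"), "w") as fh:
        json.dump(
            {
                "rate": float(raw.info["sfreq"]),
                "channel_names": list(raw.ch_names),
                "channel_roles": roles,
            },
            fh,
        )


if __name__ == "__main__":
    if len(sys.argv) != 4:
        raise SystemExit(__doc__)
    main(sys.argv[1], sys.argv[2], sys.argv[3])
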