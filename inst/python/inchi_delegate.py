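"""InChI generation delegate.

Reads a multi-record SDF (V2000, explicit hydrogens) on stdin and writes one
JSON object per record on stdout:

    {"index": 1, "inchi": "...", "auxinfo": "...", "warnings": [...],
     "error": null}

The InChI canonicalization itself is delegated to the IUPAC InChI library
bundled with RDKit; this script only shuttles structures in and results out.
Invoked with --version it prints the delegate identification string and
exits.
"""

import io
import json
import sys

from rdkit import Chem, rdBase
from rdkit.Chem import inchi
import rdkit

DELEGATE = "rdkit-" + rdkit.__version__ + "/inchi-1(bundled)"


def split_records(text):
    rec, out = [], []
    for line in text.split("\n"):
        if line.strip() == "$$$$":
            out.append("\n".join(rec))
            rec = []
        else:
            rec.append(line)
    if any(l.strip() for l in rec):
        out.append("\n".join(rec))
    return out


def process(block):
    rdBase.LogToPythonStderr()
    buf = io.StringIO()
    old = sys.stderr
    sys.stderr = buf
    try:
        mol = Chem.MolFromMolBlock(block, removeHs=False, sanitize=True)
        if mol is None:
            return None, None, buf.getvalue(), "molblock rejected by delegate"
        res = inchi.MolToInchiAndAuxInfo(mol)
        if res is None or res[0] is None or res[0] == "":
            return None, None, buf.getvalue(), "InChI generation failed"
        return res[0], res[1], buf.getvalue(), None
    except Exception as exc:  # pragma: no cover - defensive
        return None, None, buf.getvalue(), str(exc)
    finally:
        sys.stderr = old


def main():
    if "--version" in sys.argv[1:]:
        sys.stdout.write(DELEGATE + "\n")
        return 0
    text = sys.stdin.read()
    for i, block in enumerate(split_records(text), start=1):
        ichi, aux, log, err = process(block)
        warnings = [w.strip() for w in log.split("\n") if w.strip()]
        sys.stdout.write(json.dumps({
            "index": i,
            "inchi": ichi,
            "auxinfo": aux,
            "warnings": warnings,
            "error": err,
            "delegate": DELEGATE,
        }) + "\n")
    return 0


if __name__ == "__main__":
    sys.exit(main())
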