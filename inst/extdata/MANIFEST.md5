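9ec18cef9047cfce831d68c809291023 published_control_contributions.tsv
ed10f8901e6c76cce858d321ca3557d2 published_affected_contributions.tsv
5466480dc8364035c5ce4c0ff9f71ef0 published_ancestor_ttests.tsv
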