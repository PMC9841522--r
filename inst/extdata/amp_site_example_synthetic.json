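{"version":1,"min_required":2,"features":[{"kind":"acceptor_site","x":0,"y":0,"z":0,"radius":1.4},{"kind":"acceptor_site","x":7,"y":0,"z":0,"radius":1.4},{"kind":"donor_site","x":0,"y":7,"z":0,"radius":1.4},{"kind":"donor_site","x":7,"y":7,"z":0,"radius":1.4}],"exclusions":[{"x":3.5,"y":3.5,"z":4,"radius":1.4},{"x":-5,"y":-5,"z":0,"radius":1.4}]}
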