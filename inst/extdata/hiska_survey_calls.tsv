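pdb_id	subunit	conformer	rotamer
3DGE	1	.	trans
3DGE	2	.	trans
5UHT	1	.	gauche-
5UHT	2	.	gauche-
2C2A	1	.	gauche-
2C2A	2	.	gauche-
4JAU	1	.	gauche-
4JAU	2	.	trans
4JAS	1	.	gauche-
4JAS	2	.	gauche-
4JAV	1	.	gauche-
4JAV	2	A	gauche-
4JAV	2	B	trans
4I5S	1	.	trans
4I5S	2	.	gauche-
4U7N	1	.	gauche-
4U7N	2	.	trans
5C93	1	A	gauche-
5C93	1	B	trans
5C93	2	.	trans
4U7O	1	.	trans
4U7O	2	.	trans
4ZKI	1	.	trans
4ZKI	2	.	gauche-
3ZRV	1	.	trans
3ZRV	2	.	trans
3ZRX	1	.	trans
3ZRX	2	.	trans
3ZRW	1	.	trans
3ZRW	2	.	trans
5B1N	1	.	trans
5B1N	2	.	trans
5B1O	1	.	trans
5B1O	2	.	trans
4KP4	1	.	trans
4KP4	2	.	trans
4BIU	1	.	trans
4BIU	2	.	trans
4BIW	1	.	trans
4BIW	2	.	gauche-
5LFK	1	.	trans
5LFK	2	.	trans
4BIV	1	.	trans
4BIV	2	.	gauche-
4CB0	1	.	trans
4CB0	2	.	gauche-
4BIX	1	.	gauche-
4BIX	2	.	gauche-
4BIY	1	.	gauche-
4BIY	2	.	gauche-
4CTI	1	.	trans
4CTI	2	.	trans
4CTI	3	.	trans
4CTI	4	.	trans
5UKV	1	.	gauche-
5UKV	2	.	gauche-
4MT8	1	.	gauche-
4MT8	2	.	trans
6DK7	1	.	trans
6DK7	2	.	trans
6DK7	3	.	trans
6DK7	4	.	trans
6DK7	5	.	gauche-
6DK7	6	.	gauche-
6DK7	7	.	gauche-
6DK7	8	.	gauche-
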