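384
Tt 0 1 10 55 1
Tt 1 2 11 56 1
Tt 2 3 12 57 1
Tt 3 4 13 58 1
Tt 4 5 14 59 1
Tt 5 6 15 60 1
Tt 6 7 16 61 1
Tt 7 8 17 62 1
Tt 9 10 19 64 1
Tt 10 11 20 65 1
Tt 11 12 21 66 1
Tt 12 13 22 67 1
Tt 13 14 23 68 1
Tt 14 15 24 69 1
Tt 15 16 25 70 1
Tt 16 17 26 71 1
Tt 18 19 28 73 1
Tt 19 20 29 74 1
Tt 20 21 30 75 1
Tt 21 22 31 76 1
Tt 22 23 32 77 1
Tt 23 24 33 78 1
Tt 24 25 34 79 1
Tt 25 26 35 80 1
Tt 27 28 37 82 1
Tt 28 29 38 83 1
Tt 29 30 39 84 1
Tt 30 31 40 85 1
Tt 31 32 41 86 1
Tt 32 33 42 87 1
Tt 33 34 43 88 1
Tt 34 35 44 89 1
Tt 45 46 55 100 1
Tt 46 47 56 101 1
Tt 47 48 57 102 1
Tt 48 49 58 103 1
Tt 49 50 59 104 1
Tt 50 51 60 105 1
Tt 51 52 61 106 1
Tt 52 53 62 107 1
Tt 54 55 64 109 1
Tt 55 56 65 110 1
Tt 56 57 66 111 1
Tt 57 58 67 112 1
Tt 58 59 68 113 1
Tt 59 60 69 114 1
Tt 60 61 70 115 1
Tt 61 62 71 116 1
Tt 63 64 73 118 1
Tt 64 65 74 119 1
Tt 65 66 75 120 1
Tt 66 67 76 121 1
Tt 67 68 77 122 1
Tt 68 69 78 123 1
Tt 69 70 79 124 1
Tt 70 71 80 125 1
Tt 72 73 82 127 1
Tt 73 74 83 128 1
Tt 74 75 84 129 1
Tt 75 76 85 130 1
Tt 76 77 86 131 1
Tt 77 78 87 132 1
Tt 78 79 88 133 1
Tt 79 80 89 134 1
Tt 0 1 55 46 1
Tt 1 2 56 47 1
Tt 2 3 57 48 1
Tt 3 4 58 49 1
Tt 4 5 59 50 1
Tt 5 6 60 51 1
Tt 6 7 61 52 1
Tt 7 8 62 53 1
Tt 9 10 64 55 1
Tt 10 11 65 56 1
Tt 11 12 66 57 1
Tt 12 13 67 58 1
Tt 13 14 68 59 1
Tt 14 15 69 60 1
Tt 15 16 70 61 1
Tt 16 17 71 62 1
Tt 18 19 73 64 1
Tt 19 20 74 65 1
Tt 20 21 75 66 1
Tt 21 22 76 67 1
Tt 22 23 77 68 1
Tt 23 24 78 69 1
Tt 24 25 79 70 1
Tt 25 26 80 71 1
Tt 27 28 82 73 1
Tt 28 29 83 74 1
Tt 29 30 84 75 1
Tt 30 31 85 76 1
Tt 31 32 86 77 1
Tt 32 33 87 78 1
Tt 33 34 88 79 1
Tt 34 35 89 80 1
Tt 45 46 100 91 1
Tt 46 47 101 92 1
Tt 47 48 102 93 1
Tt 48 49 103 94 1
Tt 49 50 104 95 1
Tt 50 51 105 96 1
Tt 51 52 106 97 1
Tt 52 53 107 98 1
Tt 54 55 109 100 1
Tt 55 56 110 101 1
Tt 56 57 111 102 1
Tt 57 58 112 103 1
Tt 58 59 113 104 1
Tt 59 60 114 105 1
Tt 60 61 115 106 1
Tt 61 62 116 107 1
Tt 63 64 118 109 1
Tt 64 65 119 110 1
Tt 65 66 120 111 1
Tt 66 67 121 112 1
Tt 67 68 122 113 1
Tt 68 69 123 114 1
Tt 69 70 124 115 1
Tt 70 71 125 116 1
Tt 72 73 127 118 1
Tt 73 74 128 119 1
Tt 74 75 129 120 1
Tt 75 76 130 121 1
Tt 76 77 131 122 1
Tt 77 78 132 123 1
Tt 78 79 133 124 1
Tt 79 80 134 125 1
Tt 0 9 55 10 1
Tt 1 10 56 11 1
Tt 2 11 57 12 1
Tt 3 12 58 13 1
Tt 4 13 59 14 1
Tt 5 14 60 15 1
Tt 6 15 61 16 1
Tt 7 16 62 17 1
Tt 9 18 64 19 1
Tt 10 19 65 20 1
Tt 11 20 66 21 1
Tt 12 21 67 22 1
Tt 13 22 68 23 1
Tt 14 23 69 24 1
Tt 15 24 70 25 1
Tt 16 25 71 26 1
Tt 18 27 73 28 1
Tt 19 28 74 29 1
Tt 20 29 75 30 1
Tt 21 30 76 31 1
Tt 22 31 77 32 1
Tt 23 32 78 33 1
Tt 24 33 79 34 1
Tt 25 34 80 35 1
Tt 27 36 82 37 1
Tt 28 37 83 38 1
Tt 29 38 84 39 1
Tt 30 39 85 40 1
Tt 31 40 86 41 1
Tt 32 41 87 42 1
Tt 33 42 88 43 1
Tt 34 43 89 44 1
Tt 45 54 100 55 1
Tt 46 55 101 56 1
Tt 47 56 102 57 1
Tt 48 57 103 58 1
Tt 49 58 104 59 1
Tt 50 59 105 60 1
Tt 51 60 106 61 1
Tt 52 61 107 62 1
Tt 54 63 109 64 1
Tt 55 64 110 65 1
Tt 56 65 111 66 1
Tt 57 66 112 67 1
Tt 58 67 113 68 1
Tt 59 68 114 69 1
Tt 60 69 115 70 1
Tt 61 70 116 71 1
Tt 63 72 118 73 1
Tt 64 73 119 74 1
Tt 65 74 120 75 1
Tt 66 75 121 76 1
Tt 67 76 122 77 1
Tt 68 77 123 78 1
Tt 69 78 124 79 1
Tt 70 79 125 80 1
Tt 72 81 127 82 1
Tt 73 82 128 83 1
Tt 74 83 129 84 1
Tt 75 84 130 85 1
Tt 76 85 131 86 1
Tt 77 86 132 87 1
Tt 78 87 133 88 1
Tt 79 88 134 89 1
Tt 0 9 54 55 1
Tt 1 10 55 56 1
Tt 2 11 56 57 1
Tt 3 12 57 58 1
Tt 4 13 58 59 1
Tt 5 14 59 60 1
Tt 6 15 60 61 1
Tt 7 16 61 62 1
Tt 9 18 63 64 1
Tt 10 19 64 65 1
Tt 11 20 65 66 1
Tt 12 21 66 67 1
Tt 13 22 67 68 1
Tt 14 23 68 69 1
Tt 15 24 69 70 1
Tt 16 25 70 71 1
Tt 18 27 72 73 1
Tt 19 28 73 74 1
Tt 20 29 74 75 1
Tt 21 30 75 76 1
Tt 22 31 76 77 1
Tt 23 32 77 78 1
Tt 24 33 78 79 1
Tt 25 34 79 80 1
Tt 27 36 81 82 1
Tt 28 37 82 83 1
Tt 29 38 83 84 1
Tt 30 39 84 85 1
Tt 31 40 85 86 1
Tt 32 41 86 87 1
Tt 33 42 87 88 1
Tt 34 43 88 89 1
Tt 45 54 99 100 1
Tt 46 55 100 101 1
Tt 47 56 101 102 1
Tt 48 57 102 103 1
Tt 49 58 103 104 1
Tt 50 59 104 105 1
Tt 51 60 105 106 1
Tt 52 61 106 107 1
Tt 54 63 108 109 1
Tt 55 64 109 110 1
Tt 56 65 110 111 1
Tt 57 66 111 112 1
Tt 58 67 112 113 1
Tt 59 68 113 114 1
Tt 60 69 114 115 1
Tt 61 70 115 116 1
Tt 63 72 117 118 1
Tt 64 73 118 119 1
Tt 65 74 119 120 1
Tt 66 75 120 121 1
Tt 67 76 121 122 1
Tt 68 77 122 123 1
Tt 69 78 123 124 1
Tt 70 79 124 125 1
Tt 72 81 126 127 1
Tt 73 82 127 128 1
Tt 74 83 128 129 1
Tt 75 84 129 130 1
Tt 76 85 130 131 1
Tt 77 86 131 132 1
Tt 78 87 132 133 1
Tt 79 88 133 134 1
Tt 0 45 46 55 1
Tt 1 46 47 56 1
Tt 2 47 48 57 1
Tt 3 48 49 58 1
Tt 4 49 50 59 1
Tt 5 50 51 60 1
Tt 6 51 52 61 1
Tt 7 52 53 62 1
Tt 9 54 55 64 1
Tt 10 55 56 65 1
Tt 11 56 57 66 1
Tt 12 57 58 67 1
Tt 13 58 59 68 1
Tt 14 59 60 69 1
Tt 15 60 61 70 1
Tt 16 61 62 71 1
Tt 18 63 64 73 1
Tt 19 64 65 74 1
Tt 20 65 66 75 1
Tt 21 66 67 76 1
Tt 22 67 68 77 1
Tt 23 68 69 78 1
Tt 24 69 70 79 1
Tt 25 70 71 80 1
Tt 27 72 73 82 1
Tt 28 73 74 83 1
Tt 29 74 75 84 1
Tt 30 75 76 85 1
Tt 31 76 77 86 1
Tt 32 77 78 87 1
Tt 33 78 79 88 1
Tt 34 79 80 89 1
Tt 45 90 91 100 1
Tt 46 91 92 101 1
Tt 47 92 93 102 1
Tt 48 93 94 103 1
Tt 49 94 95 104 1
Tt 50 95 96 105 1
Tt 51 96 97 106 1
Tt 52 97 98 107 1
Tt 54 99 100 109 1
Tt 55 100 101 110 1
Tt 56 101 102 111 1
Tt 57 102 103 112 1
Tt 58 103 104 113 1
Tt 59 104 105 114 1
Tt 60 105 106 115 1
Tt 61 106 107 116 1
Tt 63 108 109 118 1
Tt 64 109 110 119 1
Tt 65 110 111 120 1
Tt 66 111 112 121 1
Tt 67 112 113 122 1
Tt 68 113 114 123 1
Tt 69 114 115 124 1
Tt 70 115 116 125 1
Tt 72 117 118 127 1
Tt 73 118 119 128 1
Tt 74 119 120 129 1
Tt 75 120 121 130 1
Tt 76 121 122 131 1
Tt 77 122 123 132 1
Tt 78 123 124 133 1
Tt 79 124 125 134 1
Tt 0 45 55 54 1
Tt 1 46 56 55 1
Tt 2 47 57 56 1
Tt 3 48 58 57 1
Tt 4 49 59 58 1
Tt 5 50 60 59 1
Tt 6 51 61 60 1
Tt 7 52 62 61 1
Tt 9 54 64 63 1
Tt 10 55 65 64 1
Tt 11 56 66 65 1
Tt 12 57 67 66 1
Tt 13 58 68 67 1
Tt 14 59 69 68 1
Tt 15 60 70 69 1
Tt 16 61 71 70 1
Tt 18 63 73 72 1
Tt 19 64 74 73 1
Tt 20 65 75 74 1
Tt 21 66 76 75 1
Tt 22 67 77 76 1
Tt 23 68 78 77 1
Tt 24 69 79 78 1
Tt 25 70 80 79 1
Tt 27 72 82 81 1
Tt 28 73 83 82 1
Tt 29 74 84 83 1
Tt 30 75 85 84 1
Tt 31 76 86 85 1
Tt 32 77 87 86 1
Tt 33 78 88 87 1
Tt 34 79 89 88 1
Tt 45 90 100 99 1
Tt 46 91 101 100 1
Tt 47 92 102 101 1
Tt 48 93 103 102 1
Tt 49 94 104 103 1
Tt 50 95 105 104 1
Tt 51 96 106 105 1
Tt 52 97 107 106 1
Tt 54 99 109 108 1
Tt 55 100 110 109 1
Tt 56 101 111 110 1
Tt 57 102 112 111 1
Tt 58 103 113 112 1
Tt 59 104 114 113 1
Tt 60 105 115 114 1
Tt 61 106 116 115 1
Tt 63 108 118 117 1
Tt 64 109 119 118 1
Tt 65 110 120 119 1
Tt 66 111 121 120 1
Tt 67 112 122 121 1
Tt 68 113 123 122 1
Tt 69 114 124 123 1
Tt 70 115 125 124 1
Tt 72 117 127 126 1
Tt 73 118 128 127 1
Tt 74 119 129 128 1
Tt 75 120 130 129 1
Tt 76 121 131 130 1
Tt 77 122 132 131 1
Tt 78 123 133 132 1
Tt 79 124 134 133 1
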